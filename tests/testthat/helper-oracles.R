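# Brute-force enumeration oracles, independent of the package's recursive
# likelihood implementation.  All oracles sum over explicit genotype
# (carrier) assignments of every member of a structure.

# flatten a normal_tree into a parent-index vector (root's parent = 0,
# meaning "the obligate carrier above the tree")
flatten_tree <- function(tree) {
  parent <- integer(0)
  walk <- function(node, pidx) {
    parent[length(parent) + 1L] <<- pidx
    idx <- length(parent)
    for (ch in node$children) walk(ch, idx)
  }
  walk(tree, 0L)
  parent
}

# joint probability of a carrier-state assignment and all-normal phenotypes
tree_state_prob <- function(parent, s, k) {
  p <- 1
  for (i in seq_along(parent)) {
    ps <- if (parent[i] == 0L) 1L else s[parent[i]]
    if (ps == 1L) {
      p <- p * 0.5
    } else if (s[i] == 1L) {
      return(0)  # child of a non-carrier cannot carry
    }
    if (s[i] == 1L) p <- p * (1 - k)  # carrier observed normal
    if (p == 0) return(0)
  }
  p
}

# P(all members of the tree phenotypically normal | root's parent carries)
oracle_tree_prob <- function(tree, k) {
  parent <- flatten_tree(tree)
  states <- as.matrix(expand.grid(rep(list(0:1), length(parent))))
  sum(apply(states, 1, tree_state_prob, parent = parent, k = k))
}

# P(member i carries | all members normal), for every member, preorder
oracle_tree_het <- function(tree, k) {
  parent <- flatten_tree(tree)
  n <- length(parent)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  joint <- numeric(n)
  tot <- 0
  for (r in seq_len(nrow(states))) {
    p <- tree_state_prob(parent, states[r, ], k)
    tot <- tot + p
    joint <- joint + p * states[r, ]
  }
  joint / tot
}

# twin-pair class probabilities by enumeration over zygosity, genotypes and
# phenotype outcomes; returns c(both_normal, discordant, both_affected)
oracle_twin_probs <- function(k, m) {
  probs <- c(both_normal = 0, discordant = 0, both_affected = 0)
  for (zyg in c("mz", "dz")) {
    pz <- if (zyg == "mz") m else 1 - m
    genos <- if (zyg == "mz") {
      list(list(g = c(0, 0), p = 0.5), list(g = c(1, 1), p = 0.5))
    } else {
      apply(expand.grid(0:1, 0:1), 1,
            function(g) list(g = as.integer(g), p = 0.25))
    }
    for (ge in genos) {
      for (a1 in 0:1) {
        for (a2 in 0:1) {
          ph <- function(g, a) {
            if (g == 1L) (if (a == 1L) k else 1 - k)
            else (if (a == 1L) 0 else 1)
          }
          cls <- c("both_normal", "discordant", "both_affected")[a1 + a2 + 1L]
          probs[cls] <- probs[cls] +
            pz * ge$p * ph(ge$g[1], a1) * ph(ge$g[2], a2)
        }
      }
    }
  }
  probs
}

# P(twin 1 carries | observed class), twin 1 being the normal member
oracle_twin_het <- function(class, k, m) {
  num <- 0
  den <- 0
  a2 <- if (class == "both_normal") 0L else 1L
  for (zyg in c("mz", "dz")) {
    pz <- if (zyg == "mz") m else 1 - m
    genos <- if (zyg == "mz") {
      list(list(g = c(0, 0), p = 0.5), list(g = c(1, 1), p = 0.5))
    } else {
      apply(expand.grid(0:1, 0:1), 1,
            function(g) list(g = as.integer(g), p = 0.25))
    }
    for (ge in genos) {
      ph <- function(g, a) {
        if (g == 1L) (if (a == 1L) k else 1 - k)
        else (if (a == 1L) 0 else 1)
      }
      p <- pz * ge$p * ph(ge$g[1], 0L) * ph(ge$g[2], a2)
      den <- den + p
      if (ge$g[1] == 1L) num <- num + p
    }
  }
  num / den
}

# exact log P(all phenotypes | designated founder carries, penetrance k) by
# enumeration over the carrier states of every blood descendant
oracle_pedigree_ll <- function(ped, k) {
  df <- ped$individuals
  origin <- df$id[df$designated]
  stopifnot(length(origin) == 1L)
  blood <- setdiff(penetrance:::descendants_of(ped, origin), character(0))
  states <- as.matrix(expand.grid(rep(list(0:1), length(blood))))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    carrier <- stats::setNames(rep(0L, nrow(df)), df$id)
    carrier[origin] <- 1L
    carrier[blood] <- states[r, ]
    p <- 1
    for (i in seq_len(nrow(df))) {
      id <- df$id[i]
      if (id %in% blood) {
        ncp <- carrier[df$father[i]] + carrier[df$mother[i]]
        pc <- 1 - 0.5^ncp
        p <- p * (if (carrier[id] == 1L) pc else 1 - pc)
      }
      if (p == 0) break
      ph <- df$phenotype[i]
      if (ph == "unknown") next
      p <- p * if (carrier[id] == 1L) {
        if (ph == "affected") k else 1 - k
      } else {
        if (ph == "affected") 0 else 1
      }
      if (p == 0) break
    }
    tot <- tot + p
  }
  as.numeric(log(tot))
}

# catalogue of normal-tree shapes up to depth 4 and 6 members, as dialect
# serializations
tree_catalogue <- function() {
  lapply(c("1", "2", "3", "5",
           "(1)", "(2)", "(1,0)", "(2,1)", "(3,0)", "(1,1,0)",
           "((1))", "((1),0)", "((2))", "((1,0))", "((1),1)"),
         penetrance:::tree_from_string)
}

# quick inline pedigree builder
quick_ped <- function(..., family_id = "T") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], father = r[[2]], mother = r[[3]], sex = r[[4]],
               phenotype = r[[5]],
               twin = if (length(r) >= 6) r[[6]] else NA_character_,
               designated = if (length(r) >= 7) r[[7]] else FALSE,
               stringsAsFactors = FALSE)
  }))
  pedigree(df, family_id = family_id)
}

counts_sig <- function(x) penetrance:::counts_signature(x)
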