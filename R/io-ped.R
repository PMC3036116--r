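#' Read a pedigree from a LINKAGE/PED file
#'
#' Reads the standard 6-column pre-makeped LINKAGE dialect: family id,
#' individual id, father id, mother id, sex, phenotype, whitespace-separated.
#' \code{0} codes a missing parent; sex is \code{1} = male, \code{2} = female,
#' \code{0} = unknown; phenotype is \code{1} = normal, \code{2} = affected,
#' \code{0} = unknown.  Extra columns are ignored with a warning.
#'
#' Twin pairs and the designated carrier founder are not expressible in
#' standard PED; they live in an optional sidecar annotation file (YAML),
#' e.g.
#' \preformatted{
#' carrier: I-1
#' twins:
#'   pair1: [III-2, III-3]
#' }
#'
#' @param path path to the PED file.
#' @param annotations optional path to the sidecar YAML annotation file.
#' @return a validated \code{pen_pedigree}.  If the file contains several
#'   families, only the first is returned, with a warning.
#' @export
read_ped <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("PED file '", path, "' contains no records")
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1]
    stop("PED parse error at line ", lineno[bad], ": expected 6 columns, got ",
         nf[bad])
  }
  if (any(nf > 6L)) {
    warning("PED file '", path, "': extra columns beyond 6 ignored")
  }
  rec <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  fams <- unique(rec[, 1])
  if (length(fams) > 1L) {
    warning("PED file contains ", length(fams), " families; using '",
            fams[1], "'")
    rec <- rec[rec[, 1] == fams[1], , drop = FALSE]
  }
  decode <- function(x, map, what, ln) {
    out <- map[x]
    if (anyNA(out)) {
      bad <- which(is.na(out))[1]
      stop("PED parse error at line ", ln[bad], ": invalid ", what, " code '",
           x[bad], "'")
    }
    unname(out)
  }
  ln <- lineno[rec[, 1] == fams[1]]
  df <- data.frame(
    id = rec[, 2],
    father = ifelse(rec[, 3] == "0", NA_character_, rec[, 3]),
    mother = ifelse(rec[, 4] == "0", NA_character_, rec[, 4]),
    sex = decode(rec[, 5], c(`1` = "male", `2` = "female", `0` = "unknown"),
                 "sex", ln),
    phenotype = decode(rec[, 6], c(`1` = "normal", `2` = "affected",
                                   `0` = "unknown"), "phenotype", ln),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    if (length(ann$carrier) > 0L) {
      miss <- setdiff(ann$carrier, df$id)
      if (length(miss) > 0L) {
        stop("annotation error: designated carrier '", miss[1],
             "' not in pedigree")
      }
      df$designated <- df$id %in% ann$carrier
    }
    if (length(ann$twins) > 0L) {
      df$twin <- NA_character_
      for (pair in names(ann$twins)) {
        members <- as.character(ann$twins[[pair]])
        miss <- setdiff(members, df$id)
        if (length(miss) > 0L) {
          stop("annotation error: twin '", miss[1], "' not in pedigree")
        }
        df$twin[df$id %in% members] <- pair
      }
    }
  }
  pedigree(df, family_id = fams[1])
}

read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- yaml::read_yaml(path)
  out <- list(carrier = character(0), twins = list())
  if (!is.null(ann$carrier)) out$carrier <- as.character(ann$carrier)
  if (!is.null(ann$twins)) {
    if (is.null(names(ann$twins))) {
      stop("annotation error: 'twins' must map pair labels to id pairs")
    }
    bad <- which(lengths(ann$twins) != 2L)
    if (length(bad) > 0L) {
      stop("annotation error: twin pair '", names(ann$twins)[bad[1]],
           "' must list exactly two ids")
    }
    out$twins <- ann$twins
  }
  out
}

#' Write a pedigree to a LINKAGE/PED file
#'
#' Inverse of [read_ped()].  Twin pairs and the designated carrier, which
#' standard PED cannot express, are written to a sidecar YAML file when
#' \code{annotations} is given (and must be, if the pedigree has any).
#'
#' @param ped a \code{pen_pedigree}.
#' @param path output PED path.
#' @param annotations optional path for the sidecar annotation file.
#' @return \code{path}, invisibly.
#' @export
write_ped <- function(ped, path, annotations = NULL) {
  df <- ped$individuals
  enc_sex <- c(male = "1", female = "2", unknown = "0")
  enc_phe <- c(normal = "1", affected = "2", unknown = "0")
  rec <- cbind(
    ped$family_id, df$id,
    ifelse(is.na(df$father), "0", df$father),
    ifelse(is.na(df$mother), "0", df$mother),
    enc_sex[df$sex], enc_phe[df$phenotype]
  )
  writeLines(apply(rec, 1, paste, collapse = " "), path)
  has_ann <- any(df$designated) || any(!is.na(df$twin))
  if (has_ann && is.null(annotations)) {
    warning("pedigree has twin/carrier annotations but no annotation path ",
            "was given; they are not representable in PED and were dropped")
  }
  if (!is.null(annotations)) {
    ann <- list()
    if (any(df$designated)) ann$carrier <- df$id[df$designated]
    pairs <- unique(df$twin[!is.na(df$twin)])
    if (length(pairs) > 0L) {
      ann$twins <- stats::setNames(
        lapply(pairs, function(p) df$id[!is.na(df$twin) & df$twin == p]),
        pairs
      )
    }
    yaml::write_yaml(ann, annotations)
  }
  invisible(path)
}
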