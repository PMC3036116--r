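#' Example pedigrees
#'
#' Hard-coded example pedigrees used throughout the documentation and tests.
#'
#' \describe{
#' \item{\code{"fig1"}}{A four-generation pedigree segregating an autosomal
#'   dominant condition: three affected individuals (II-4, III-4, IV-1),
#'   four obligate non-penetrant carriers (I-1, II-1, II-3, III-1), two
#'   childless normal offspring of carriers (II-5, II-6) and two
#'   2-generation trees of normal individuals (II-2 with III-2 and III-3;
#'   III-5 with IV-2 to IV-4).  The carrier founder I-1 is designated.
#'   Its structure counts are A=3, B=4, C=2 with 2-generation trees of 2 and
#'   3 offspring.}
#' \item{\code{"fig5"}}{A pedigree with one consanguineous loop: first
#'   cousins II-1 and II-2 (grandchildren of the designated founder P-1, via
#'   I-1 and Q-1 respectively) have a child III-1 whose son IV-2 is
#'   affected.  The allele may have reached IV-2 through I-1 or through
#'   II-2, so the loop splits into two configurations.  Q-1 also has an
#'   affected child R-1, which makes Q-1 an obligate carrier under every
#'   configuration.}
#' \item{\code{"two_loops"}}{A pedigree with two independent consanguineous
#'   loops (two sibling matings among children of the designated founder
#'   couple, each with an affected grandchild), giving 2 x 2 = 4
#'   configuration combinations.}
#' }
#'
#' @param name one of \code{"fig1"}, \code{"fig5"}, \code{"two_loops"}.
#' @return a \code{pen_pedigree}.
#' @export
#' @examples
#' extract_structures(make_fixture("fig1"))
make_fixture <- function(name) {
  name <- match.arg(name, c("fig1", "fig5", "two_loops"))
  ind <- function(id, father, mother, sex, phenotype, designated = FALSE) {
    data.frame(id = id, father = father, mother = mother, sex = sex,
               phenotype = phenotype, twin = NA_character_,
               designated = designated, stringsAsFactors = FALSE)
  }
  if (name == "fig1") {
    df <- rbind(
      ind("I-1", NA, NA, "male", "normal", designated = TRUE),
      ind("I-2", NA, NA, "female", "normal"),
      ind("II-1", "I-1", "I-2", "female", "normal"),
      ind("II-2", "I-1", "I-2", "male", "normal"),
      ind("II-3", "I-1", "I-2", "female", "normal"),
      ind("II-4", "I-1", "I-2", "male", "affected"),
      ind("II-5", "I-1", "I-2", "female", "normal"),
      ind("II-6", "I-1", "I-2", "male", "normal"),
      ind("II-7", NA, NA, "male", "normal"),    # spouse of II-1
      ind("II-8", NA, NA, "female", "normal"),  # spouse of II-2
      ind("II-9", NA, NA, "male", "normal"),    # spouse of II-3
      ind("III-1", "II-7", "II-1", "female", "normal"),
      ind("III-2", "II-2", "II-8", "male", "normal"),
      ind("III-3", "II-2", "II-8", "female", "normal"),
      ind("III-4", "II-9", "II-3", "male", "affected"),
      ind("III-5", "II-9", "II-3", "female", "normal"),
      ind("III-6", NA, NA, "male", "normal"),   # spouse of III-1
      ind("III-7", NA, NA, "male", "normal"),   # spouse of III-5
      ind("IV-1", "III-6", "III-1", "male", "affected"),
      ind("IV-2", "III-7", "III-5", "male", "normal"),
      ind("IV-3", "III-7", "III-5", "female", "normal"),
      ind("IV-4", "III-7", "III-5", "male", "normal")
    )
    return(pedigree(df, family_id = "FIG1"))
  }
  if (name == "fig5") {
    df <- rbind(
      ind("P-1", NA, NA, "male", "normal", designated = TRUE),
      ind("P-2", NA, NA, "female", "normal"),
      ind("I-1", "P-1", "P-2", "female", "normal"),
      ind("I-2", NA, NA, "male", "normal"),     # spouse of I-1
      ind("Q-1", "P-1", "P-2", "male", "normal"),
      ind("Q-2", NA, NA, "female", "normal"),   # spouse of Q-1
      ind("II-1", "I-2", "I-1", "male", "normal"),
      ind("II-2", "Q-1", "Q-2", "female", "normal"),
      ind("R-1", "Q-1", "Q-2", "male", "affected"),
      ind("III-1", "II-1", "II-2", "male", "normal"),
      ind("III-2", NA, NA, "female", "normal"), # spouse of III-1
      ind("IV-1", "III-1", "III-2", "female", "normal"),
      ind("IV-2", "III-1", "III-2", "male", "affected")
    )
    return(pedigree(df, family_id = "FIG5"))
  }
  # two_loops: two sibling matings among children of the founder couple,
  # each loop with an affected grandchild of the couple
  df <- rbind(
    ind("O-1", NA, NA, "male", "normal", designated = TRUE),
    ind("O-2", NA, NA, "female", "normal"),
    ind("U-1", "O-1", "O-2", "male", "normal"),
    ind("V-1", "O-1", "O-2", "female", "normal"),
    ind("U-2", "O-1", "O-2", "male", "normal"),
    ind("V-2", "O-1", "O-2", "female", "normal"),
    ind("J-1", "U-1", "V-1", "male", "normal"),
    ind("J-2", "U-2", "V-2", "female", "normal"),
    ind("S-1", NA, NA, "female", "normal"),  # spouse of J-1
    ind("S-2", NA, NA, "male", "normal"),    # spouse of J-2
    ind("X-1", "J-1", "S-1", "male", "affected"),
    ind("X-2", "S-2", "J-2", "female", "affected")
  )
  pedigree(df, family_id = "TWOLOOPS")
}
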