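#' Oral adverse-event vocabulary
#'
#' An `ae_term_frame` maps MedDRA-style preferred terms to the
#' anatomo-physiological group they belong to (taste, sensation, lips,
#' palate, tongue, dentition, salivary glands, oral mucosa), together with
#' the exclusion keywords used to screen out terms that mention the mouth
#' without being oral-cavity adverse events (oral contraception, congenital
#' malformations, oncologic diagnoses).
#'
#' @param entries data frame with columns `term` and `group`, one row per
#'   preferred term. Terms are normalised with [normalize_term()]; groups
#'   must be one of the eight anatomical/functional groups.
#' @param exclusion_keywords character vector of case-insensitive substring
#'   keywords. No vocabulary entry may itself match a keyword.
#' @return an object of class `ae_term_frame`: a data frame `term`/`group`
#'   with the keywords in `attr(, "exclusion_keywords")`.
#' @seealso [oral_term_frame()] for the packaged 80-term vocabulary,
#'   [classify_oral_terms()] to apply it to a term universe.
#' @export
ae_term_frame <- function(entries, exclusion_keywords = character()) {
  if (!is.data.frame(entries) || !all(c("term", "group") %in% names(entries)))
    stop_domain("`entries` must be a data frame with columns term, group")
  if (nrow(entries) == 0L)
    stop_domain("term frame must be non-empty")
  entries$term <- normalize_term(entries$term)
  entries$group <- as.character(entries$group)
  bad <- setdiff(unique(entries$group), GROUP_LEVELS)
  if (length(bad))
    stop_domain("unknown group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(entries$term))
    stop_domain("duplicated terms in frame: ",
                paste(unique(entries$term[duplicated(entries$term)]), collapse = ", "))
  exclusion_keywords <- normalize_term(exclusion_keywords)
  hit <- matches_exclusion(entries$term, exclusion_keywords)
  if (any(hit))
    stop_domain("frame entries match exclusion keywords: ",
                paste(entries$term[hit], collapse = ", "))
  out <- entries[, c("term", "group")]
  rownames(out) <- NULL
  attr(out, "exclusion_keywords") <- exclusion_keywords
  class(out) <- c("ae_term_frame", "data.frame")
  out
}

matches_exclusion <- function(terms, keywords) {
  if (!length(keywords)) return(rep(FALSE, length(terms)))
  hit <- rep(FALSE, length(terms))
  for (kw in keywords) hit <- hit | grepl(kw, terms, fixed = TRUE)
  hit
}

#' Packaged oral adverse-event vocabulary
#'
#' Returns the 80-term oral AE vocabulary assembled from the published
#' PEI/VAERS surveillance summary tables: the 60 terms retained in the
#' primary analysis plus the 20 terms trimmed for having fewer than three
#' reports, each assigned to its anatomical/functional group, together with
#' the packaged exclusion keywords.
#'
#' @return an [ae_term_frame].
#' @export
#' @examples
#' frame <- oral_term_frame()
#' nrow(frame)  # 80
oral_term_frame <- function() {
  entries <- read.csv(pkg_extdata("oral_terms.csv"), stringsAsFactors = FALSE)
  kw <- readLines(pkg_extdata("exclusion_keywords.txt"))
  kw <- kw[nzchar(trimws(kw))]
  ae_term_frame(entries, kw)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "oravigil")
  if (path == "") {
    # during development (pkgload) the sources live under inst/
    path <- system.file("inst", "extdata", file, package = "oravigil")
  }
  if (path == "") stop_domain("packaged file not found: ", file)
  path
}

#' Classify a term universe against the oral vocabulary
#'
#' Keeps the terms of `term_universe` that are present in the vocabulary,
#' drops any term matching an exclusion keyword (case-insensitive substring
#' match on the normalised term), and returns the matches sorted by term.
#'
#' @param term_universe character vector of preferred terms observed in a
#'   database.
#' @param frame an [ae_term_frame].
#' @return data frame with columns `term` and `group`, sorted by term.
#' @export
#' @examples
#' frame <- oral_term_frame()
#' classify_oral_terms(c("Oral herpes", "oral contraception", "headache"), frame)
classify_oral_terms <- function(term_universe, frame) {
  stopifnot(inherits(frame, "ae_term_frame"))
  if (nrow(frame) == 0L) stop_domain("frame must be non-empty")
  u <- unique(normalize_term(term_universe))
  u <- u[!is.na(u) & nzchar(u)]
  u <- u[!matches_exclusion(u, attr(frame, "exclusion_keywords"))]
  keep <- frame[frame$term %in% u, c("term", "group")]
  keep <- keep[order(keep$term), ]
  rownames(keep) <- NULL
  keep
}
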