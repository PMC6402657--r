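# Published per-subject benchmark scores from the eight-subject, four-class
# co-adaptive online study this method was validated on, shipped as
# plain-text tables so the derived statistics (signed-rank tests, per-subject
# regression, column means) can be recomputed.

#' Published study score tables
#'
#' Per-run scores of the eight subjects of the co-adaptive online study:
#' segment-level prediction accuracy, confusion-matrix quality (both in
#' percent) over runs D1..D6, and the pairwise class-separability scores per
#' subject and run. The first four runs used constrained feedback, the last
#' two full feedback.
#'
#' @param which one of `"accuracy"`, `"qcm"`, `"separability"`
#' @return data.frame; subjects (and, for separability, class pairs) in
#'   rows, runs D1..D6 in columns
#' @export
studyScores <- function(which = c("accuracy", "qcm", "separability")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("study_", which, ".csv"),
                      package = "riemix", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
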