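#' Published reference results of the 30-subject smartwatch study
#'
#' The original 30-subject smartwatch HRV recordings that this package's
#' simulator emulates were collected privately and never deposited, so the
#' study's verification results cannot be recomputed from raw data. The
#' published summary tables are bundled instead, both as a sanity anchor
#' for the report formats this package produces and to exercise the
#' aggregation arithmetic ([mean_eer()], [success_rates()]) on real
#' numbers:
#'
#' * `"fusion_eer_per_subject"` — per-subject equal error rates (percent)
#'   of the bior1.1 approximation-fusion and detail-fusion verifiers over
#'   all 30 subjects.
#' * `"fusion_comparison"` — the best-four fusion comparison: sub-band-3
#'   and fused EERs (percent) for bior1.1 and bior1.3.
#' * `"authentication_counts"` — accepted/rejected counts for 100 patient
#'   and 2000 non-patient authentication attempts at operating thresholds
#'   of 9--12% FAR.
#'
#' @param name one of `"fusion_eer_per_subject"`, `"fusion_comparison"`,
#'   `"authentication_counts"`.
#' @return the requested reference table as a data.frame.
#' @export
#' @examples
#' mean_eer(reference_table("fusion_eer_per_subject")$detail_fusion_eer)
reference_table <- function(name = c("fusion_eer_per_subject",
                                     "fusion_comparison",
                                     "authentication_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "hrvauth", mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}
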