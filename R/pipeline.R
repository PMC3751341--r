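#' Pipeline default parameters
#'
#' The thresholds the analysis runs with unless overridden: variant
#' bounds (end shifts up to 3 nt, up to 3 added bases, up to 1
#' substitution), the `> 10` reporting count filter, the age-model and
#' regression significance levels (0.01, strict), and the
#' anti-correlation threshold (-0.70, strict). Read-preprocessing
#' defaults (adapter, overlap, mismatch tolerance, length window) are
#' included for completeness.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(max_trim = 3L,
       max_add = 3L,
       max_sub = 1L,
       min_count = 10L,
       alpha_age = 0.01,
       alpha_reg = 0.01,
       r_max = -0.70,
       adapter = TRUSEQ_SMALL_RNA_ADAPTER,
       adapter_min_overlap = 6L,
       adapter_max_mismatch_frac = 0.1,
       min_length = 16L,
       max_length = 28L,
       pseudocount = 1)
}
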