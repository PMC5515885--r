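## Two-sample testing.

#' Two-tailed Welch t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom, as used for treated-vs-intact probe-signal comparisons.
#' Thin wrapper over [stats::t.test()] returning the statistic, df and
#' two-tailed p-value.
#'
#' @param a,b numeric samples (each n >= 2, nonzero variance in at least
#'   one).
#' @return List with `t`, `df`, `p`, `meanA`, `meanB`.
#' @examples
#' welchTTest(1:5, 2:6)
#' @export
welchTTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop(npcError("npcStatsError",
                  "each sample needs at least 2 observations"))
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                meanA = mean(a), meanB = mean(b)))
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop(npcError("npcStatsError",
                  "both samples are constant; Welch df undefined"))
  ht <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanA = mean(a), meanB = mean(b))
}
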