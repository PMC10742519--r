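#' Signed expression fold change
#'
#' The expression ratio between a cancer condition and the reference,
#' reported on the symmetric signed scale: `x = ratio` when the ratio is
#' >= 1, `x = -1/ratio` otherwise, so `|x| >= 1` always and negative values
#' mean down-regulation.
#'
#' @param ave_cancer,ave_ref positive mean expressions (AVE) of the gene in
#'   the two conditions; vectorized.
#' @return signed fold change(s).
#' @export
fold_change <- function(ave_cancer, ave_ref) {
  if (any(ave_cancer <= 0) || any(ave_ref <= 0))
    stop("mean expressions must be positive")
  rho <- ave_cancer / ave_ref
  ifelse(rho >= 1, rho, -1 / rho)
}

#' Gene-specific fold-change cut-off
#'
#' The absolute fold change a gene must exceed to be called regulated,
#' combining the biological variability and platform noise of the gene in
#' both compared conditions:
#' `CUT = 1 + sqrt((REV_cancer/100)^2 + (REV_ref/100)^2)`.
#' A stably expressed gene (low REVs) gets a cut-off close to 1 — small
#' changes are detectable — while a noisy gene must move much more.
#'
#' @param rev_cancer,rev_ref relative expression variabilities in percent;
#'   vectorized.
#' @return cut-off(s) >= 1.
#' @export
cut_value <- function(rev_cancer, rev_ref) {
  if (any(rev_cancer < 0) || any(rev_ref < 0))
    stop("REV must be non-negative")
  1 + sqrt((rev_cancer / 100)^2 + (rev_ref / 100)^2)
}

#' Heteroscedastic test of differential mean expression
#'
#' Two-tailed Welch (unequal-variance) t-test on the normalized replica
#' expressions of one gene in two conditions. Degenerate input (both groups
#' constant) yields p = 1 for equal means and p = 0 otherwise.
#'
#' @param values_cancer,values_ref replicate profiles (length >= 2 each).
#' @return two-tailed p-value.
#' @export
regulation_test <- function(values_cancer, values_ref) {
  if (length(values_cancer) < 2 || length(values_ref) < 2)
    stop("need at least 2 replicas per condition")
  if (stats::sd(values_cancer) == 0 && stats::sd(values_ref) == 0)
    return(if (mean(values_cancer) == mean(values_ref)) 1 else 0)
  stats::t.test(values_cancer, values_ref, var.equal = FALSE)$p.value
}

#' Call the regulome from regulation records
#'
#' A gene is significantly regulated when its absolute fold change exceeds
#' its own cut-off *and* the heteroscedastic p-value is below `p_cut`.
#'
#' @param records data.frame with columns `x`, `CUT`, `p` (and typically
#'   `gene`, `contrast`).
#' @param p_cut p-value threshold (default 0.05).
#' @return `records` with a logical `significant` column and a `direction`
#'   column (`"up"`, `"down"`, or `NA` for non-significant genes).
#' @export
call_regulome <- function(records, p_cut = 0.05) {
  stopifnot(all(c("x", "CUT", "p") %in% names(records)))
  records$significant <- abs(records$x) > records$CUT & records$p < p_cut
  records$direction <- ifelse(records$significant,
                              ifelse(records$x > 0, "up", "down"),
                              NA_character_)
  records
}

#' Audit the uniform fold-change criterion against the adaptive one
#'
#' Compares the traditional uniform cut-off (|x| > `uniform_cut`) with the
#' gene-specific CUT rule. A *false positive* is a gene the uniform rule
#' flags but the adaptive rule does not (its change is within its own
#' noise); a *false negative* is a gene below the uniform cut-off that the
#' adaptive rule nonetheless calls significant (a stably expressed gene
#' whose small change is real).
#'
#' @param records output of [call_regulome()].
#' @param uniform_cut the uniform absolute fold-change threshold
#'   (conventionally 1.5).
#' @return `records` with logical columns `false_positive` and
#'   `false_negative`.
#' @export
false_hit_audit <- function(records, uniform_cut = 1.5) {
  stopifnot(all(c("x", "significant") %in% names(records)))
  records$false_positive <- abs(records$x) > uniform_cut & !records$significant
  records$false_negative <- abs(records$x) < uniform_cut & records$significant
  records
}

#' Weighted individual gene regulation
#'
#' `|WIR| = AVE_ref * (|x| - 1) * (1 - p)`: the regulation contribution of a
#' gene weighted by how expressed it was in the reference tissue, how much
#' its level changed, and how statistically convincing the change is. The
#' sign is carried from the fold change (negative = down-regulation).
#' Applied to all genes, significant or not.
#'
#' @param ave_ref reference-condition AVE; vectorized.
#' @param x signed fold change.
#' @param p heteroscedastic p-value.
#' @return signed WIR; exactly 0 when |x| = 1.
#' @export
wir <- function(ave_ref, x, p) {
  sign(x) * ave_ref * (abs(x) - 1) * (1 - p)
}

#' Weighted pathway regulation
#'
#' Mean of |WIR| over the quantified genes of a pathway: a pathway-level
#' alteration measure that keeps the graded contribution of every gene
#' instead of counting significant ones.
#'
#' @param wir_values signed WIR values of the pathway's quantified genes.
#' @return WPR >= 0.
#' @export
wpr <- function(wir_values) {
  if (!length(wir_values)) stop("pathway has no quantified genes")
  mean(abs(wir_values))
}
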