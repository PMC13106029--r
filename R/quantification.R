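# Downstream quantitative readouts: Trouvelot root-length colonization
# indices from per-fragment ordinal scores, and delta-delta-Ct qPCR fold
# changes.

#' Trouvelot mycorrhizal colonization indices
#'
#' Computes the standard Trouvelot indices from per-root-fragment scores:
#' F\% (frequency of colonization), M\% (intensity of colonization in the
#' whole root system), m\% (intensity within colonized fragments), a\%/A\%
#' (arbuscule abundance in colonized fragments / whole root system) and
#' v\%/V\% (vesicle abundance, analogously). Intensity classes 0-5 carry
#' the conventional weights 0, 1, 5, 30, 70, 95; arbuscule and vesicle
#' classes A0-A3 / V0-V3 carry weights 0, 10, 50, 100.
#'
#' @param fragments data.frame with one row per root fragment and columns
#'   `intensity` (integer 0-5), `arbuscule` ("A0".."A3") and `vesicle`
#'   ("V0".."V3"). A fragment with intensity 0 must be A0 and V0.
#' @return list of class `trouvelot_result` with elements `F_pct`, `M_pct`,
#'   `m_pct`, `a_pct`, `A_pct`, `v_pct`, `V_pct`, `n_fragments`.
#' @export
trouvelot_indices <- function(fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("intensity", "arbuscule", "vesicle") %in% names(fragments)))
  n <- nrow(fragments)
  if (n < 1L) stop("at least one scored root fragment is required")
  intensity <- as.integer(fragments$intensity)
  if (any(is.na(intensity)) || any(!intensity %in% 0:5)) {
    stop("intensity class must be an integer in 0..5")
  }
  arb <- match(fragments$arbuscule, paste0("A", 0:3)) - 1L
  ves <- match(fragments$vesicle, paste0("V", 0:3)) - 1L
  if (any(is.na(arb)) || any(is.na(ves))) {
    stop("arbuscule/vesicle classes must be A0..A3 / V0..V3")
  }
  if (any(intensity == 0L & (arb > 0L | ves > 0L))) {
    stop("fragments with intensity 0 cannot carry arbuscules or vesicles")
  }
  int_w <- c(0, 1, 5, 30, 70, 95)       # classes 0..5
  abund_w <- c(0, 10, 50, 100)          # classes 0..3
  colonized <- sum(intensity > 0L)
  M <- sum(int_w[intensity + 1L]) / n
  if (M == 0 && any(arb > 0L | ves > 0L)) {
    stop("invariant violation: zero colonization intensity with nonzero ",
         "arbuscule/vesicle classes")
  }
  F_pct <- 100 * colonized / n
  m_pct <- if (colonized > 0L) M * n / colonized else 0

  abundance <- function(cls) {
    if (M == 0) return(c(whole = 0, colonized = 0))
    # mA_i%: intensity-weighted share of fragments in abundance class i,
    # rescaled to colonized-intensity terms
    mA <- vapply(1:3, function(i) {
      sum(int_w[intensity[cls == i] + 1L]) / n * 100 / M
    }, numeric(1))
    a <- sum(abund_w[2:4] * mA) / 100
    c(whole = a * M / 100, colonized = a)
  }
  arb_ab <- abundance(arb)
  ves_ab <- abundance(ves)

  structure(list(F_pct = F_pct, M_pct = M, m_pct = m_pct,
                 a_pct = arb_ab[["colonized"]], A_pct = arb_ab[["whole"]],
                 v_pct = ves_ab[["colonized"]], V_pct = ves_ab[["whole"]],
                 n_fragments = n),
            class = "trouvelot_result")
}

#' @export
print.trouvelot_result <- function(x, ...) {
  cat(sprintf(
    "Trouvelot indices (n = %d fragments):\n  F%% = %.1f  M%% = %.2f  m%% = %.2f\n  a%% = %.2f  A%% = %.2f  v%% = %.2f  V%% = %.2f\n",
    x$n_fragments, x$F_pct, x$M_pct, x$m_pct, x$a_pct, x$A_pct, x$v_pct,
    x$V_pct))
  invisible(x)
}

#' Delta-delta-Ct fold changes
#'
#' Per gene: delta-Ct = Ct_target - Ct_reference per sample; delta-delta-Ct
#' = mean delta-Ct(treatment) - mean delta-Ct(control); fold change =
#' 2^(-delta-delta-Ct).
#'
#' @param measurements data.frame with columns `sample_id`, `gene_id`,
#'   `condition`, `ct_target`, `ct_reference` (Ct values in (0, 45]).
#' @param control_condition the condition used as baseline.
#' @return data.frame with one row per (gene, non-control condition):
#'   `gene_id`, `condition`, `n_control`, `n_treatment`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(measurements, control_condition) {
  need <- c("sample_id", "gene_id", "condition", "ct_target", "ct_reference")
  stopifnot(is.data.frame(measurements), all(need %in% names(measurements)))
  ct <- c(measurements$ct_target, measurements$ct_reference)
  if (any(is.na(ct)) || any(ct <= 0 | ct > 45)) {
    stop("Ct values must lie in (0, 45]; missing reference gene?")
  }
  if (!control_condition %in% measurements$condition) {
    stop("no measurements for control condition '", control_condition, "'")
  }
  measurements$dct <- measurements$ct_target - measurements$ct_reference
  out <- list()
  for (g in unique(measurements$gene_id)) {
    mg <- measurements[measurements$gene_id == g, , drop = FALSE]
    ctrl <- mg$dct[mg$condition == control_condition]
    if (!length(ctrl)) stop("gene '", g, "' has no control measurements")
    for (cond in setdiff(unique(mg$condition), control_condition)) {
      trt <- mg$dct[mg$condition == cond]
      ddct <- mean(trt) - mean(ctrl)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, condition = cond, n_control = length(ctrl),
        n_treatment = length(trt), delta_delta_ct = ddct,
        fold_change = 2^(-ddct), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no non-control measurements found")
  do.call(rbind, out)
}
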