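#' Relative expression by the comparative CT method
#'
#' Classic comparative threshold-cycle quantification assuming 100%
#' amplification efficiency (doubling per cycle):
#' \deqn{\Delta C_T(g) = \bar{C_T}(g) - \bar{C_T}(ref), \quad
#'       \Delta\Delta C_T = \Delta C_T(target) - \Delta C_T(calibrator),
#'       \quad fold = 2^{-\Delta\Delta C_T}.}
#' The replicate standard deviations of target and reference are combined
#' in quadrature (the calibrator's mean enters as the arbitrary constant
#' of the method), and the fold interval is the point estimate mapped
#' through \eqn{2^{-(\Delta\Delta C_T \pm s)}}.
#'
#' @param ct Data frame of replicate threshold cycles with columns
#'   `gene`, `replicate`, `ct`.
#' @param target Target gene id(s); defaults to every gene except
#'   reference and calibrator.
#' @param reference Reference (housekeeping) gene id, e.g. the 28S rRNA
#'   gene.
#' @param calibrator Calibrator gene id (fold is expressed relative to
#'   it).
#' @param efficiency Amplification factor per cycle (default 2; an
#'   efficiency-corrected analysis can pass `1 + E`).
#' @return Data frame with one row per target: `gene`, `n_reps`, `dct`,
#'   `ddct`, `sd_ddct`, `fold`, `fold_lo`, `fold_hi`.
#' @export
ddct_fold <- function(ct, target = NULL, reference = "28S", calibrator,
                      efficiency = 2) {
  req <- c("gene", "replicate", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("all CT values must be positive and finite", call. = FALSE)
  genes <- unique(ct$gene)
  if (!reference %in% genes)
    stop("reference gene '", reference, "' has no replicates",
         call. = FALSE)
  if (!calibrator %in% genes)
    stop("calibrator gene '", calibrator, "' has no replicates",
         call. = FALSE)
  if (is.null(target)) target <- setdiff(genes, reference)
  missing_t <- setdiff(target, genes)
  if (length(missing_t))
    stop("target gene(s) missing from table: ",
         paste(missing_t, collapse = ", "), call. = FALSE)

  mean_of <- tapply(ct$ct, ct$gene, mean)
  sd_of <- tapply(ct$ct, ct$gene, function(x) {
    if (length(x) > 1) sd(x) else 0
  })
  n_of <- tapply(ct$ct, ct$gene, length)

  dct <- mean_of - mean_of[[reference]]
  ddct <- unname(dct[target] - dct[[calibrator]])
  # identical replicate sets must give fold exactly 1
  ddct[target == calibrator] <- 0
  sd_ddct <- sqrt(unname(sd_of[target])^2 + sd_of[[reference]]^2)
  fold <- efficiency^(-ddct)
  data.frame(
    gene = target,
    n_reps = as.integer(unname(n_of[target])),
    dct = unname(dct[target]),
    ddct = ddct,
    sd_ddct = sd_ddct,
    fold = fold,
    fold_lo = efficiency^(-(ddct + sd_ddct)),
    fold_hi = efficiency^(-(ddct - sd_ddct)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a CT replicate table
#'
#' Tab-separated with a header row `gene<TAB>replicate<TAB>ct`.
#'
#' @param path File path.
#' @return Data frame suitable for [ddct_fold()].
#' @export
read_ct_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
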