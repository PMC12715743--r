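## Linear QSRR (quantitative structure-retention relationship) model:
## fixed 2D descriptor set, forward stepwise selection by leave-one-out
## RMSE, ordinary least squares on the selected subset.

QSRR_DESCRIPTORS <- c("mw", "logp", "tpsa", "hbd", "hba", "molar_refractivity",
                      "heavy_atoms", "rings", "aromatic_rings", "n_fluorine")

#' Compute 2D molecular descriptors from a SMILES string
#'
#' A fixed, documented descriptor set computed with Open Babel (via
#' ChemmineR/ChemmineOB): molecular weight, calculated logP (lipophilicity),
#' topological polar surface area, H-bond donor and acceptor counts, molar
#' refractivity, heavy-atom count, ring and aromatic-ring counts, and
#' fluorine count. Deterministic for a given structure.
#'
#' @param smiles One or more SMILES strings.
#' @return `data.frame` with one row per structure and the columns of
#'   `QSRR_DESCRIPTORS`.
#' @export
compute_descriptors <- function(smiles) {
  if (!is.character(smiles) || !length(smiles) || any(!nzchar(smiles)) ||
      anyNA(smiles))
    stop("smiles must be non-empty strings")
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop("unparseable structure: ",
                                           conditionMessage(e)))
  if (length(sdf) != length(smiles))
    stop("one or more structures could not be parsed")
  ## propOB keys rows by molecule title; compute per molecule so unnamed
  ## structures do not collide
  pr <- do.call(rbind, lapply(seq_along(smiles), function(i)
    ChemmineR::propOB(sdf[i])))
  rg <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  if (is.null(dim(rg))) rg <- matrix(rg, nrow = 1,
                                     dimnames = list(NULL, names(rg)))
  heavy <- vapply(pr$formula, function(f) {
    counts <- parse_formula(f)
    sum(counts) - counts[["H"]] - counts[["D"]]
  }, numeric(1))
  out <- data.frame(
    mw = pr$MW, logp = pr$logP, tpsa = pr$TPSA, hbd = pr$HBD,
    hba = pr$HBA1, molar_refractivity = pr$MR, heavy_atoms = heavy,
    rings = as.numeric(rg[, "RINGS"]),
    aromatic_rings = as.numeric(rg[, "AROMATIC"]),
    n_fluorine = pr$nF)
  rownames(out) <- NULL
  if (any(!is.finite(as.matrix(out))))
    stop("descriptor computation produced non-finite values")
  out
}

## leave-one-out RMSE of an OLS fit, via the hat matrix (PRESS residuals)
.loo_rmse <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, as.matrix(X)), y)
  h <- stats::hat(cbind(1, as.matrix(X)), intercept = FALSE)
  r <- fit$residuals / (1 - h)
  if (any(!is.finite(r))) return(Inf)
  sqrt(mean(r^2))
}

#' Fit a linear QSRR retention-time model
#'
#' Descriptors are selected by forward stepwise search minimizing the
#' leave-one-out RMSE (ties broken lexicographically by descriptor name,
#' so the fit is independent of row and column order), then refit by
#' ordinary least squares. Descriptors that would make the design
#' rank-deficient are skipped with a warning.
#'
#' @param descriptors `data.frame`/matrix of descriptors (rows = training
#'   compounds), or a character vector of SMILES (descriptors are then
#'   computed internally).
#' @param rt Measured retention times, minutes.
#' @param max_descriptors Maximum number of selected descriptors
#'   (default 4); `n >= max_descriptors + 2` is required.
#' @return An object of class `qsrr` with components `coefficients`,
#'   `selected`, `fitted.values`, `residuals`, `r.squared`,
#'   `rmse`, `loo_rmse`, `n`.
#' @examples
#' \donttest{
#' std <- paraben_compounds()
#' fit <- fit_qsrr(std$smiles, std$rt, max_descriptors = 2)
#' predict(fit, "CCCOC(=O)c1ccc(O)cc1")
#' }
#' @export
fit_qsrr <- function(descriptors, rt, max_descriptors = 4L) {
  if (is.character(descriptors)) descriptors <- compute_descriptors(descriptors)
  X <- as.data.frame(descriptors)
  n <- nrow(X)
  if (length(rt) != n) stop("rt length must match descriptor rows")
  if (n < max_descriptors + 2)
    stop("need at least max_descriptors + 2 training compounds (have ",
         n, ")")
  pool <- sort(colnames(X))
  selected <- character(0)
  best_rmse <- sqrt(mean((rt - mean(rt))^2))  # intercept-only baseline
  repeat {
    if (length(selected) >= max_descriptors) break
    scores <- vapply(setdiff(pool, selected), function(d) {
      Xs <- as.matrix(X[, c(selected, d), drop = FALSE])
      if (qr(cbind(1, Xs))$rank < ncol(Xs) + 1) return(Inf)
      .loo_rmse(Xs, rt)
    }, numeric(1))
    if (!length(scores) || min(scores) >= best_rmse - 1e-12) break
    pick <- names(scores)[which.min(scores)]  # names are sorted: ties lexicographic
    selected <- c(selected, pick)
    best_rmse <- min(scores)
  }
  form_X <- as.matrix(X[, selected, drop = FALSE])
  keep <- qr(cbind(1, form_X))$rank == ncol(form_X) + 1
  if (!keep && length(selected)) {
    warning("collinear descriptor set; dropping to a full-rank subset")
    while (length(selected) &&
           qr(cbind(1, as.matrix(X[, selected, drop = FALSE])))$rank <
             length(selected) + 1)
      selected <- selected[-length(selected)]
    form_X <- as.matrix(X[, selected, drop = FALSE])
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, form_X), rt)
  fitted <- as.numeric(cbind(1, form_X) %*% fit$coefficients)
  res <- rt - fitted
  ss_tot <- sum((rt - mean(rt))^2)
  structure(list(coefficients = fit$coefficients, selected = selected,
                 fitted.values = fitted, residuals = res,
                 r.squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1,
                 rmse = sqrt(mean(res^2)), loo_rmse = best_rmse, n = n,
                 descriptor_names = colnames(X)),
            class = "qsrr")
}

#' @export
print.qsrr <- function(x, ...) {
  cat("Linear QSRR retention-time model\n")
  cat(sprintf("  n = %d, selected descriptors: %s\n", x$n,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  R^2 = %.4f, RMSE = %.3f min, LOO-RMSE = %.3f min\n",
              x$r.squared, x$rmse, x$loo_rmse))
  cat("Coefficients (min per unit):\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.qsrr <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.qsrr <- function(object, ...) object$coefficients

#' @export
residuals.qsrr <- function(object, ...) object$residuals

#' Predict retention times from a QSRR model
#'
#' @param object A fitted `qsrr` model.
#' @param newdata Descriptor data.frame (same columns as training) or a
#'   character vector of SMILES.
#' @param ... Unused.
#' @return Predicted retention times, minutes.
#' @export
predict.qsrr <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- compute_descriptors(newdata)
  X <- as.matrix(as.data.frame(newdata)[, object$selected, drop = FALSE])
  as.numeric(cbind(1, X) %*% object$coefficients)
}

#' @method plot qsrr
#' @export
plot.qsrr <- function(x, ...) {
  obs <- x$fitted.values + x$residuals
  graphics::plot(x$fitted.values, obs, xlab = "predicted RT (min)",
                 ylab = "measured RT (min)",
                 main = sprintf("QSRR fit (R^2 = %.3f)", x$r.squared), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Retention-time gap between model and observation
#'
#' @param model A fitted `qsrr` model.
#' @param structure SMILES string or one-row descriptor data.frame.
#' @param observed_rt Measured retention time, minutes.
#' @return List with `predicted_rt` and `delta_rt = |observed - predicted|`.
#' @export
delta_rt <- function(model, structure, observed_rt) {
  pred <- predict(model, structure)
  list(predicted_rt = pred, delta_rt = abs(observed_rt - pred))
}

#' Serialize a QSRR model to a plain-text coefficient file
#' @param model A `qsrr` object.
#' @param path Output path.
#' @return For `read_qsrr`, a `qsrr` object usable with [predict.qsrr()].
#' @export
write_qsrr <- function(model, path) {
  df <- data.frame(term = names(model$coefficients),
                   coefficient = as.numeric(model$coefficients))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qsrr
#' @export
read_qsrr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  co <- stats::setNames(df$coefficient, df$term)
  structure(list(coefficients = co,
                 selected = setdiff(names(co), "(Intercept)"),
                 fitted.values = numeric(0), residuals = numeric(0),
                 r.squared = NA_real_, rmse = NA_real_, loo_rmse = NA_real_,
                 n = NA_integer_, descriptor_names = NA_character_),
            class = "qsrr")
}
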