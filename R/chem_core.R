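#' @keywords internal
"_PACKAGE"

## Monoisotopic atomic masses (u). D is deuterium, counted as H for RDBE.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177812,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' Parse a molecular formula in Hill notation
#'
#' Accepts formulas over the element alphabet C, H, D, N, O, S (e.g.
#' `"C7H6O3"`, `"C6D3O3"`). A named integer vector may also be supplied and
#' is validated and returned in canonical form.
#'
#' @param x A formula string in Hill notation, or a named integer vector of
#'   element counts.
#' @return Named integer vector of element counts over `c("C","H","D","N","O","S")`.
#' @examples
#' parse_formula("C7H6O3")
#' @export
parse_formula <- function(x) {
  elements <- names(ATOMIC_MASS)
  if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% elements))
      stop("formula counts must be named with elements among ",
           paste(elements, collapse = ", "))
    counts <- stats::setNames(integer(length(elements)), elements)
    counts[names(x)] <- as.integer(round(x))
  } else {
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
      stop("formula must be a single non-empty string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(x))
      stop("unparseable formula: '", x, "'")
    counts <- stats::setNames(integer(length(elements)), elements)
    for (tok in toks) {
      sym <- sub("[0-9]+$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!sym %in% elements)
        stop("unknown element '", sym, "' in formula '", x, "'")
      counts[sym] <- counts[sym] + n
    }
  }
  if (any(counts < 0)) stop("negative element count")
  if (sum(counts) == 0L) stop("empty formula")
  counts
}

#' Render element counts as a Hill-notation string
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return A single string, carbon first, then hydrogen (with D appended
#'   after H), then the remaining elements alphabetically.
#' @export
format_formula <- function(counts) {
  counts <- parse_formula(counts)
  ord <- c("C", "H", "D", "N", "O", "S")
  parts <- vapply(ord, function(el) {
    n <- counts[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts[nzchar(parts)], collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic atomic masses (C = 12 exactly,
#' H = 1.007825, D = 2.014102, O = 15.994915, S = 31.972071). The electron
#' mass is never included: ion m/z values in this package are computed on
#' the atomic-mass scale (see [mz_deprotonated()]).
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C7H6O3") # 138.031694
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * ATOMIC_MASS[names(counts)])
}

#' m/z of the deprotonated molecular ion [M-H]-
#'
#' Subtracts one hydrogen-atom mass (1.007825 u) from the neutral
#' monoisotopic mass and neglects the electron mass. This hydrogen-atom
#' convention reproduces the printed diagnostic m/z values of the
#' negative-mode HCD pathway (137.0239 for 4-hydroxybenzoate, not the
#' 137.0244 obtained by subtracting a proton and adding an electron); the
#' two conventions differ by a systematic 2 x m_e = 0.0011 Da on the ion,
#' i.e. the electron mass 0.00055 Da relative to the hydrogen-atom
#' subtraction.
#'
#' @param neutral Neutral formula (string or counts); must contain at least
#'   one H or D to abstract.
#' @return m/z in Th.
#' @examples
#' mz_deprotonated("C7H6O3") # 137.0239, 4-hydroxybenzoate
#' @export
mz_deprotonated <- function(neutral) {
  counts <- parse_formula(neutral)
  if (counts[["H"]] + counts[["D"]] < 1L)
    stop("no abstractable hydrogen: [M-H]- requires at least one H (or D)")
  monoisotopic_mass(counts) - ATOMIC_MASS[["H"]]
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values (Th); `theoretical` must be > 0.
#' @return Signed ppm error, `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

#' Ring and double bond equivalents
#'
#' RDBE = C - (H + D)/2 + N/2 + 1, computed on the neutral-formula basis.
#' Radical fragment ions are not subjected to RDBE screening; the bound is
#' applied to precursor composition only.
#'
#' @param formula Formula string or named count vector.
#' @return Dimensionless, possibly half-integral.
#' @examples
#' rdbe("C7H6O3") # 5
#' @export
rdbe <- function(formula) {
  counts <- parse_formula(formula)
  counts[["C"]] - (counts[["H"]] + counts[["D"]]) / 2 + counts[["N"]] / 2 + 1
}

#' Elemental composition constraints for formula decomposition
#'
#' Defaults are the workflow's precursor composition restrictions:
#' 7-30 C, 6-60 H, 3-10 O, 0-1 S, RDBE 5-10, 5 ppm mass tolerance.
#'
#' @param C,H,O,S Integer length-2 `(min, max)` count ranges.
#' @param rdbe Length-2 numeric RDBE range.
#' @param tolerance_ppm Mass tolerance (ppm), > 0.
#' @return An object of class `element_bounds`.
#' @export
element_bounds <- function(C = c(7L, 30L), H = c(6L, 60L), O = c(3L, 10L),
                           S = c(0L, 1L), rdbe = c(5, 10),
                           tolerance_ppm = 5) {
  b <- list(C = as.integer(C), H = as.integer(H), O = as.integer(O),
            S = as.integer(S), rdbe = as.numeric(rdbe),
            tolerance_ppm = as.numeric(tolerance_ppm))
  for (el in c("C", "H", "O", "S", "rdbe")) {
    if (length(b[[el]]) != 2L || b[[el]][1] > b[[el]][2])
      stop("invalid range for ", el)
  }
  if (b$tolerance_ppm <= 0) stop("tolerance must be > 0")
  structure(b, class = "element_bounds")
}

#' Bounded decomposition of an [M-H]- m/z into neutral formulas
#'
#' Enumerates every CHOS neutral formula within the element-count bounds
#' whose deprotonated m/z lies within `bounds$tolerance_ppm` of `mz` and
#' whose RDBE lies within `bounds$rdbe`. Equivalent to brute-force nested
#' enumeration over all in-bound element counts; the hydrogen count is
#' solved from the mass residual for speed.
#'
#' Candidates are ordered by |ppm error|, then by even-electron sanity
#' (integral non-negative RDBE first), then lexicographically by formula.
#'
#' @param mz Observed m/z of a deprotonated ion (Th).
#' @param bounds An [element_bounds()] object.
#' @return `data.frame` with columns `formula`, `mass_error_ppm`, `rdbe`
#'   (zero rows when nothing fits -- a valid result, not an error).
#' @examples
#' decompose_mass(137.0239, element_bounds())
#' @export
decompose_mass <- function(mz, bounds = element_bounds()) {
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0) stop("mz must be > 0")
  if (!inherits(bounds, "element_bounds")) stop("bounds must be element_bounds")
  target <- mz + ATOMIC_MASS[["H"]]     # neutral monoisotopic mass
  tol_da <- bounds$tolerance_ppm * 1e-6 * mz
  mH <- ATOMIC_MASS[["H"]]
  out <- vector("list", 64L); k <- 0L
  for (nS in bounds$S[1]:bounds$S[2]) {
    for (nC in bounds$C[1]:bounds$C[2]) {
      for (nO in bounds$O[1]:bounds$O[2]) {
        resid <- target - nC * 12 - nO * ATOMIC_MASS[["O"]] - nS * ATOMIC_MASS[["S"]]
        if (resid < bounds$H[1] * mH - tol_da) next
        h_lo <- max(bounds$H[1], as.integer(ceiling((resid - tol_da) / mH)))
        h_hi <- min(bounds$H[2], as.integer(floor((resid + tol_da) / mH)))
        if (h_lo > h_hi) next
        for (nH in h_lo:h_hi) {
          counts <- c(C = nC, H = nH, D = 0L, N = 0L, O = nO, S = nS)
          r <- nC - nH / 2 + 1
          if (r < bounds$rdbe[1] || r > bounds$rdbe[2]) next
          err <- ppm_error(mz, monoisotopic_mass(counts) - mH)
          ## re-check on the ppm axis (the window above is in Da)
          if (abs(err) > bounds$tolerance_ppm) next
          k <- k + 1L
          out[[k]] <- data.frame(formula = format_formula(counts),
                                 mass_error_ppm = err, rdbe = r,
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(formula = character(), mass_error_ppm = numeric(),
                      rdbe = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  senior_ok <- res$rdbe >= 0 & res$rdbe == floor(res$rdbe)
  res <- res[order(abs(res$mass_error_ppm), !senior_ok, res$formula), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
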