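## Diagnostic-ion knowledge base for the negative-mode HCD fragmentation of
## parabens (4-hydroxybenzoate esters), alkyl protocatechuates
## (3,4-dihydroxybenzoate esters) and the corresponding phenolic acids.
##
## Ion labels follow the pathway nomenclature: the A/B/C/D/E series derives
## from the paraben backbone, the F/G/H/J/K series from the ring-hydroxylated
## protocatechuate backbone; B3, C (= G2), D2 and E are shared between the
## two series.

.registry_ion_table <- function() {
  ## label, ion composition, radical anion?, parent node, neutral/radical
  ## loss formula, loss kind, classes, usable for screening?
  ions <- list(
    ## paraben series
    list("A1", "C7H5O3", FALSE, "precursor", NA,       "R-olefin", "paraben",                  TRUE),
    list("A2", "C7H4O3", TRUE,  "precursor", NA,       "R-radical", "paraben",                 TRUE),
    list("A3", "C7H4O3", TRUE,  "A2",        NA,       "rearrangement", "paraben",             FALSE),
    list("B1", "C6H5O",  FALSE, "A1",        "CO2",    "neutral", "paraben",                   TRUE),
    list("B2", "C6H4O",  TRUE,  "A2",        "CO2",    "neutral", "paraben",                   TRUE),
    list("B3", "C6H3O",  FALSE, "B2",        "H",      "radical", "paraben,protocatechuate",   TRUE),
    list("C",  "C6H4O2", TRUE,  "A3",        "CO",     "neutral", "paraben,protocatechuate",   TRUE),
    list("D2", "C6H3O3", FALSE, "A2",        "CH",     "neutral", "paraben,protocatechuate",   TRUE),
    list("E",  "C5H3O2", FALSE, "D2",        "CO",     "neutral", "paraben,protocatechuate",   TRUE),
    ## protocatechuate series
    list("F1", "C7H5O4", FALSE, "precursor", NA,       "R-olefin", "protocatechuate",          TRUE),
    list("F2", "C7H4O4", TRUE,  "precursor", NA,       "R-radical", "protocatechuate",         TRUE),
    list("F3", "C7H4O4", TRUE,  "F2",        NA,       "rearrangement", "protocatechuate",     FALSE),
    list("G1", "C6H5O2", FALSE, "F1",        "CO2",    "neutral", "protocatechuate",           TRUE),
    list("G3", "C6H3O2", FALSE, "C",         "H",      "radical", "protocatechuate",           TRUE),
    list("D1", "C6H4O3", TRUE,  "F3",        "CO",     "neutral", "protocatechuate",           TRUE),
    list("H",  "C6H3O4", FALSE, "F2",        "CH",     "neutral", "protocatechuate",           TRUE),
    list("J",  "C5H3O3", FALSE, "H",         "CO",     "neutral", "protocatechuate",           TRUE),
    list("K",  "C4H3O2", FALSE, "J",         "CO",     "neutral", "protocatechuate",           TRUE)
  )
  df <- do.call(rbind, lapply(ions, function(x)
    data.frame(label = x[[1]], formula = x[[2]], radical = x[[3]],
               parent = x[[4]], loss = x[[5]], loss_kind = x[[6]],
               classes = x[[7]], screening = x[[8]],
               stringsAsFactors = FALSE)))
  df$mz <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df
}

## secondary pathway edges beyond each ion's formation edge (shared sinks)
.registry_extra_edges <- function() {
  data.frame(
    parent = c("G1",  "D1", "F1",  "G2"),
    child  = c("B3",  "D2", "G1",  "G3"),
    loss   = c("H2O", "H",  "CO2", "H"),
    stringsAsFactors = FALSE)
}

#' Build the diagnostic fragment-ion registry
#'
#' Encodes the HCD fragmentation-pathway graph of deprotonated parabens and
#' alkyl protocatechuates, with one row per labeled product ion (A1..K).
#' Every m/z is computed from the stored ion composition, never hard-coded,
#' so deuterated analogs and conjugates can be derived by formula
#' arithmetic. Construction verifies mass balance on every pathway edge
#' (parent mass - loss mass = fragment mass, radical losses included) and
#' aborts on any inconsistency.
#'
#' The registry also carries the class screening sets used for precursor
#' prioritization: a 3-ion common set (91.0184, 95.0133, 108.0211), four
#' paraben extras (92.0262, 93.0340, 136.0160, 137.0239) and five
#' protocatechuate extras (109.0290, 111.0082, 124.0160, 152.0110,
#' 153.0188), plus per-compound applicability exceptions: methyl and benzyl
#' paraben cannot lose [R-H] as an olefin, so A1 -- and its decarboxylation
#' product B1 -- are excluded for MeP and BzP.
#'
#' @return An object of class `dfi_registry`: a data.frame (label, formula,
#'   radical, mz, parent, loss, classes, screening) with screening-set and
#'   exclusion attributes.
#' @examples
#' reg <- build_registry()
#' reg[reg$label == "E", "mz"] # 95.0133
#' @export
build_registry <- function() {
  df <- .registry_ion_table()
  rownames(df) <- df$label
  ## mass-balance audit over formation edges with a registry parent
  loss_mass <- function(loss) {
    if (is.na(loss)) 0 else monoisotopic_mass(loss)
  }
  for (i in seq_len(nrow(df))) {
    p <- df$parent[i]
    if (p == "precursor" || is.na(df$loss[i]) && p != "precursor") {
      if (p != "precursor") {
        ## rearrangement: same composition as parent
        if (abs(df$mz[i] - df[p, "mz"]) > 1e-9)
          stop("registry mass-balance failure at ", df$label[i])
      }
      next
    }
    expect <- df[p, "mz"] - loss_mass(df$loss[i])
    if (abs(expect - df$mz[i]) > 1e-3)
      stop("registry mass-balance failure at ", df$label[i])
  }
  extra <- .registry_extra_edges()
  for (i in seq_len(nrow(extra))) {
    p <- sub("G2", "C", extra$parent[i])  # G2 shares the C composition
    ch <- sub("G2", "C", extra$child[i])
    expect <- df[p, "mz"] - loss_mass(extra$loss[i])
    if (abs(expect - df[ch, "mz"]) > 1e-3)
      stop("registry mass-balance failure on edge ", extra$parent[i],
           " -> ", extra$child[i])
  }
  structure(df,
            common_set = c("B3", "E", "C"),
            paraben_extra = c("B2", "B1", "A2", "A1"),
            protocatechuate_extra = c("G1", "J", "D1", "F2", "F1"),
            characteristic_paraben = c("A1", "A2", "B1", "B2", "B3",
                                       "C", "D2", "E"),
            exclusions = list(MeP = c("A1", "B1"), BzP = c("A1", "B1")),
            extra_edges = extra,
            class = c("dfi_registry", "data.frame"))
}

#' @export
print.dfi_registry <- function(x, ...) {
  cat("Diagnostic fragment-ion registry:", nrow(x), "ions,",
      sum(x$screening), "screening-usable\n")
  print.data.frame(x[, c("label", "formula", "radical", "mz", "parent",
                         "loss", "classes")], digits = 8, ...)
  invisible(x)
}

#' Class-specific diagnostic screening set
#'
#' Returns the common diagnostic ions plus the class extras, minus any
#' per-compound applicability exclusions (A1 and B1 for MeP and BzP, whose
#' structure forbids the olefin [R-H] loss that forms A1).
#'
#' @param registry A [build_registry()] object.
#' @param compound_class `"paraben"` or `"protocatechuate"`.
#' @param compound Optional specific compound name (e.g. `"MeP"`).
#' @return Subset of the registry rows (one per diagnostic ion).
#' @examples
#' nrow(diagnostic_set(build_registry(), "paraben"))        # 7
#' nrow(diagnostic_set(build_registry(), "protocatechuate")) # 8
#' @export
diagnostic_set <- function(registry, compound_class, compound = NULL) {
  stopifnot(inherits(registry, "dfi_registry"))
  if (!compound_class %in% c("paraben", "protocatechuate"))
    stop("unknown compound class '", compound_class, "'")
  labels <- c(attr(registry, "common_set"),
              attr(registry, paste0(compound_class, "_extra")))
  if (!is.null(compound)) {
    excl <- attr(registry, "exclusions")[[compound]]
    labels <- setdiff(labels, excl)
  }
  out <- registry[registry$label %in% labels, , drop = FALSE]
  class(out) <- "data.frame"
  out
}

#' Deuterated analog of a registry ion
#'
#' Substitutes `ring_deuteriums` ring hydrogens with deuterium and
#' recomputes the m/z; used to screen for isotopically labeled internal
#' standards (e.g. PrP-d4), whose fragments mirror the unlabeled pathway
#' with ring-H losses becoming ring-D losses.
#'
#' @param ion One registry row (or a label looked up in `registry`).
#' @param ring_deuteriums Number of ring positions labeled; must not exceed
#'   the hydrogens available in the fragment formula.
#' @param registry Registry to look labels up in (default [build_registry()]).
#' @return A one-row data.frame like the registry row, with updated
#'   `formula` and `mz`.
#' @examples
#' deuterated_analog("A1", 4)$mz # 141.0490
#' @export
deuterated_analog <- function(ion, ring_deuteriums, registry = build_registry()) {
  if (is.character(ion)) {
    if (!ion %in% registry$label) stop("unknown ion label '", ion, "'")
    ion <- registry[registry$label == ion, , drop = FALSE]
  }
  counts <- parse_formula(ion$formula)
  k <- as.integer(ring_deuteriums)
  if (k < 0) stop("ring_deuteriums must be >= 0")
  if (k > counts[["H"]])
    stop("cannot substitute ", k, " deuteriums: only ", counts[["H"]],
         " hydrogens in ", ion$formula)
  counts[["H"]] <- counts[["H"]] - k
  counts[["D"]] <- counts[["D"]] + k
  out <- ion
  class(out) <- "data.frame"
  out$formula <- format_formula(counts)
  out$mz <- monoisotopic_mass(counts)
  out
}

## masses of the phase II conjugation increments on the neutral molecule
CONJUGATION_DELTA <- list(
  sulfate = "SO3",          # +79.9568
  glucuronide = "C6H8O6",   # +176.0321
  glycine = "C2H3NO"        # amide with glycine: -OH +NHCH2COOH, +57.0215
)

#' Expected [M-H]- m/z of a phase II conjugate
#'
#' Sulfation adds SO3, glucuronidation adds C6H8O6, and glycine conjugation
#' of a benzoic acid replaces the carboxyl -OH with -NH-CH2-COOH, a net
#' +C2H3NO (the hippurate relationship).
#'
#' @param free_form Neutral formula of the free (unconjugated) compound.
#' @param conjugation `"sulfate"`, `"glucuronide"` or `"glycine"`.
#' @return m/z (Th) of the deprotonated conjugate.
#' @examples
#' conjugate_mass("C8H8O3", "sulfate") # MeP sulfate, 230.9963
#' @export
conjugate_mass <- function(free_form, conjugation) {
  if (!conjugation %in% names(CONJUGATION_DELTA))
    stop("unknown conjugation '", conjugation, "'")
  counts <- parse_formula(free_form)
  delta <- parse_formula(CONJUGATION_DELTA[[conjugation]])
  mz_deprotonated(counts + delta[names(counts)])
}

#' Export or import the registry as a plain-text table
#'
#' The CSV carries label, formula, radical flag, m/z, formation edge and
#' classes so the registry can be extended to other homologous series.
#'
#' @param registry A `dfi_registry`.
#' @param path File path.
#' @return `read_registry_csv` returns a `dfi_registry` rebuilt from the
#'   table (m/z recomputed from formulas).
#' @export
write_registry_csv <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$mz <- vapply(df$formula, monoisotopic_mass, numeric(1))
  rownames(df) <- df$label
  ref <- build_registry()
  attrs <- attributes(ref)[c("common_set", "paraben_extra",
                             "protocatechuate_extra",
                             "characteristic_paraben", "exclusions",
                             "extra_edges")]
  attributes(df) <- c(attributes(df), attrs)
  class(df) <- c("dfi_registry", "data.frame")
  df
}

## marker ions observed for sulfate conjugates: the SO3 radical anion and
## hydrogensulfate (m/z on the atomic-mass scale, electron neglected)
SULFATE_MARKERS <- c(SO3 = monoisotopic_mass("SO3"),
                     HSO4 = monoisotopic_mass("HSO4"))
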