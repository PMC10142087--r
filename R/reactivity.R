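#' HOMO-LUMO gap
#'
#' Absolute difference between the highest-occupied and lowest-unoccupied
#' molecular-orbital energies. Units are carried through from the input
#' unchanged. A LUMO below the HOMO (possible with sign/unit ambiguity in
#' supplied tables) triggers a warning, not an error.
#'
#' @param homo,lumo Numeric orbital energies (vectorized).
#' @return Non-negative gap, same units as the input.
#' @examples
#' orbital_gap(-0.224, -0.0589)  # 0.1651
#' @export
orbital_gap <- function(homo, lumo) {
  if (any(is.na(homo)) || any(is.na(lumo)))
    stop("missing orbital energy", call. = FALSE)
  if (any(lumo < homo))
    warning("LUMO below HOMO for some compounds; check signs/units")
  abs(homo - lumo)
}

#' Chemical hardness
#'
#' Half the HOMO-LUMO gap, reported positive. A smaller hardness marks a
#' softer, more reactive molecule.
#'
#' @inheritParams orbital_gap
#' @return Hardness (eta) >= 0.
#' @examples
#' hardness(-0.224, -0.0589)  # 0.08255
#' @export
hardness <- function(homo, lumo) {
  orbital_gap(homo, lumo) / 2
}

#' Chemical softness
#'
#' Reciprocal of the chemical hardness, `S = 1 / eta`. Zero hardness has
#' undefined softness and is returned as `NA` with a warning.
#'
#' @param eta Numeric hardness values.
#' @return Softness values; `NA` where `eta == 0`.
#' @export
softness <- function(eta) {
  if (any(eta < 0)) stop("hardness must be non-negative", call. = FALSE)
  out <- ifelse(eta > 0, 1 / eta, NA_real_)
  if (any(eta == 0))
    warning("zero hardness: softness undefined, returned as NA")
  out
}

#' Frontier-orbital reactivity comparison
#'
#' Computes gap, hardness and softness for a candidate panel and a set
#' of standard drugs, and flags every candidate whose hardness is
#' strictly below that of *every* standard — the softer-than-all rule
#' (softness boosts chemical reactivity, so such candidates are the most
#' reactive in the panel). Equality with a standard does not flag.
#'
#' @param candidates,standards Data frames with columns `compound_id`,
#'   `homo`, `lumo` (see [gen_orbitals()] / [standard_orbitals()]).
#' @return Data frame with one row per compound: `compound_id`, `role`,
#'   `homo`, `lumo`, `gap`, `hardness`, `softness`,
#'   `softer_than_all_standards`.
#' @export
reactivity_report <- function(candidates, standards) {
  stopifnot(is.data.frame(candidates), is.data.frame(standards))
  if (nrow(candidates) < 1L) stop("no candidate compounds", call. = FALSE)
  if (nrow(standards) < 1L) stop("no standard compounds", call. = FALSE)
  one <- function(df, role) {
    eta <- hardness(df$homo, df$lumo)
    data.frame(compound_id = as.character(df$compound_id), role = role,
               homo = df$homo, lumo = df$lumo,
               gap = orbital_gap(df$homo, df$lumo),
               hardness = eta, softness = softness(eta),
               stringsAsFactors = FALSE)
  }
  cand <- one(candidates, "candidate")
  std <- one(standards, "standard")
  min_std <- min(std$hardness)
  cand$softer_than_all_standards <- cand$hardness < min_std
  std$softer_than_all_standards <- FALSE
  out <- rbind(cand, std)
  rownames(out) <- NULL
  out
}

#' Read an orbital-energy CSV
#' @param path CSV with columns `compound_id`, `homo`, `lumo`
#'   (optionally `units`).
#' @return Data frame.
#' @export
read_orbitals_csv <- function(path) {
  if (!file.exists(path)) stop("orbital file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
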