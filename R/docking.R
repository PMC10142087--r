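#' Compare candidate docking scores against reference ligands
#'
#' For every (candidate ligand, target) pair, compares the docking score
#' (kcal/mol, more negative = stronger) with the reference ligands
#' docked on the same target and classifies the candidate:
#'
#' * `comparable` — within `comparable_margin` (default 0.5 kcal/mol) of
#'   the best (most negative) reference score;
#' * `stronger_than_all_references` — more negative than every reference
#'   score and outside the comparable band;
#' * `weaker` — otherwise.
#'
#' Independently, a candidate is flagged a strong binder when its score
#' is strictly below `strong_threshold` (default -8 kcal/mol; a score of
#' exactly -8 is not flagged).
#'
#' @param records Data frame with columns `ligand`, `target`,
#'   `score_kcal_mol` (optionally `target_pdb`).
#' @param references Character vector of reference ligand names.
#' @param strong_threshold Strong-binder cutoff in kcal/mol.
#' @param comparable_margin Half-width of the comparable band, kcal/mol.
#' @return Data frame with one row per candidate-target pair: `ligand`,
#'   `target`, `score_kcal_mol`, `best_reference`,
#'   `best_reference_score`, `classification`, `strong_binder`.
#' @examples
#' compare_docking_scores(example_docking_scores())
#' @export
compare_docking_scores <- function(records,
                                   references = c("Aspirin", "Indomethacin"),
                                   strong_threshold = -8,
                                   comparable_margin = 0.5) {
  stopifnot(is.data.frame(records))
  if (!all(is.finite(records$score_kcal_mol)))
    stop("docking scores must be finite", call. = FALSE)
  if ("target_pdb" %in% names(records)) {
    bad <- !grepl("^[A-Za-z0-9]{4}$", records$target_pdb)
    if (any(bad))
      warning("non-standard PDB ids: ",
              paste(unique(records$target_pdb[bad]), collapse = ", "))
  }
  is_ref <- records$ligand %in% references
  cand <- records[!is_ref, , drop = FALSE]
  refs <- records[is_ref, , drop = FALSE]
  if (!nrow(cand)) stop("no candidate records", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    tg <- cand$target[i]
    r <- refs[refs$target == tg, , drop = FALSE]
    if (!nrow(r))
      stop("no reference scores for target ", tg, call. = FALSE)
    best <- which.min(r$score_kcal_mol)
    sc <- cand$score_kcal_mol[i]
    cls <- if (abs(sc - r$score_kcal_mol[best]) <= comparable_margin) {
      "comparable"
    } else if (sc < min(r$score_kcal_mol)) {
      "stronger_than_all_references"
    } else {
      "weaker"
    }
    data.frame(ligand = cand$ligand[i], target = tg,
               score_kcal_mol = sc,
               best_reference = r$ligand[best],
               best_reference_score = r$score_kcal_mol[best],
               classification = cls,
               strong_binder = sc < strong_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a docking-score CSV
#' @param path CSV with columns `ligand`, `target`, `score_kcal_mol`
#'   (optionally `target_pdb`).
#' @return Data frame.
#' @export
read_docking_csv <- function(path) {
  if (!file.exists(path)) stop("docking file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
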