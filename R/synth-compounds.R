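#' Generate a synthetic screened-metabolite table
#'
#' Emulates a GC-MS compound table joined with ADME descriptors: one row
#' per metabolite with retention time, peak area, a synthetic structure
#' string, and the five quantities the drug-likeness screen consumes
#' (molecular weight, H-bond acceptor/donor counts, Moriguchi logP, and
#' the discrete Abbott oral-bioavailability score).
#'
#' Exactly `floor(frac_violators * n)` rows are planted with at least two
#' rule-of-five violations (so they fail the screen); every other row has
#' at most one violation and a bioavailability level above 0.50, so it
#' passes. Descriptors stay in physically plausible ranges: MW 50-900 Da,
#' HBA 0-15, HBD 0-8, MLOGP -3 to 7.
#'
#' @param n Number of compounds.
#' @param frac_violators Fraction of rows planted as screen failures.
#' @param seed Integer seed; identical calls are byte-identical.
#' @return A data frame with columns `id`, `name`, `formula`, `rt_min`,
#'   `area_pct`, `smiles`, `mw`, `hba`, `hbd`, `mlogp`, `bioavailability`.
#' @examples
#' head(gen_compounds(5, 0, seed = 1))
#' @export
gen_compounds <- function(n, frac_violators = 0, seed = 1L) {
  n <- check_count(n, "n")
  frac_violators <- check_fraction(frac_violators, "frac_violators")
  cols <- c("id", "name", "formula", "rt_min", "area_pct", "smiles",
            "mw", "hba", "hbd", "mlogp", "bioavailability")
  if (n == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$rt_min <- out$area_pct <- out$mw <- out$mlogp <- out$bioavailability <- numeric(0)
    out$hba <- out$hbd <- integer(0)
    return(out)
  }
  # Abbott bioavailability score is discrete; levels above 0.50 pass the gate
  ob_levels <- c(0.11, 0.17, 0.55, 0.56, 0.85)
  ob_pass <- c(0.55, 0.56, 0.85)
  with_local_seed(seed, {
    n_viol <- as.integer(floor(frac_violators * n))
    viol_idx <- if (n_viol > 0L) sort(sample.int(n, n_viol)) else integer(0)

    mw    <- round(stats::runif(n, 80, 480), 1)
    hba   <- sample(0:9, n, replace = TRUE)
    hbd   <- pmin(hba, sample(0:4, n, replace = TRUE))
    mlogp <- round(stats::runif(n, -3, 4.0), 2)
    ob    <- sample(ob_pass, n, replace = TRUE)

    # a third of the clean rows carry exactly one violation: still drug-like
    one_viol <- setdiff(which(stats::runif(n) < 1 / 3), viol_idx)
    if (length(one_viol)) {
      rule <- sample(4L, length(one_viol), replace = TRUE)
      mw[one_viol][rule == 1L]    <- round(stats::runif(sum(rule == 1L), 501, 900), 1)
      hba[one_viol][rule == 2L]   <- sample(11:15, sum(rule == 2L), replace = TRUE)
      hbd[one_viol][rule == 3L]   <- sample(6:8, sum(rule == 3L), replace = TRUE)
      mlogp[one_viol][rule == 4L] <- round(stats::runif(sum(rule == 4L), 4.2, 7), 2)
    }
    for (i in viol_idx) {
      rules <- sample(4L, sample(2:4, 1L))
      if (1L %in% rules) mw[i]    <- round(stats::runif(1, 501, 900), 1)
      if (2L %in% rules) hba[i]   <- sample(11:15, 1L)
      if (3L %in% rules) hbd[i]   <- sample(6:8, 1L)
      if (4L %in% rules) mlogp[i] <- round(stats::runif(1, 4.2, 7), 2)
      ob[i] <- sample(ob_levels, 1L)
    }

    nc <- pmax(4L, round(mw / 14))
    data.frame(
      id      = sprintf("cmp%03d", seq_len(n)),
      name    = sprintf("synthetic-metabolite-%03d", seq_len(n)),
      formula = sprintf("C%dH%dO%d", nc, nc + sample(2:8, n, replace = TRUE),
                        sample(1:6, n, replace = TRUE)),
      rt_min   = round(sort(stats::runif(n, 2, 45)), 2),
      area_pct = round(as.numeric(stats::rmultinom(1, 1000, rep(1, n))) / 10, 2),
      smiles   = vapply(nc, synth_smiles, character(1)),
      mw = mw, hba = hba, hbd = hbd, mlogp = mlogp, bioavailability = ob,
      stringsAsFactors = FALSE
    )
  })
}

# toy linear-chain SMILES; syntactically plausible, chemically meaningless
synth_smiles <- function(len) {
  atoms <- sample(c("C", "C", "C", "O", "N"), min(len, 20L), replace = TRUE)
  paste0(paste(atoms, collapse = ""), "(=O)O")
}
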