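# Shared builders and the brute-force DSA matching oracle.

mk_panel <- function(specs, mfis, serum_id = "s1", ...) {
  sab_panel(data.frame(bead_id = sprintf("b%02d", seq_along(specs)),
                       specificity = specs, raw_mfi = mfis,
                       stringsAsFactors = FALSE),
            serum_id = serum_id, ...)
}

# Independent brute-force matcher: enumerates every (donor entry, bead) pair,
# classifies the pair with its own small predicates, then assembles calls with
# the documented two-pass claiming (exact claims first, then antigen-level;
# surrogates reuse beads). Used to cross-check identify_dsa.
oracle_identify <- function(donor, panel, cutoffs,
                            equivalence = hla_equivalence()) {
  entries <- donor$entries
  beads <- panel$beads
  cutoff <- vapply(beads$locus, function(l) {
    if (l %in% names(cutoffs$per_locus)) cutoffs$per_locus[[l]]
    else cutoffs$global
  }, numeric(1))
  positive <- beads$raw_mfi >= cutoff

  is_molecular2 <- function(x) {
    !inherits(x, "hla_heterodimer") && is.null(x$antigen) &&
      length(x$fields) == 2L
  }
  eqv <- function(x) serologic_equivalents(x, equivalence)
  grp <- function(x) {
    if (inherits(x, "hla_heterodimer")) x <- x$beta
    if (is.null(x$antigen) && length(x$fields) >= 1L) antigen_group(x)
    else NA_character_
  }
  pair_exact <- function(e, b) {
    if (inherits(e, "hla_heterodimer") && inherits(b, "hla_heterodimer")) {
      format(e) == format(b)
    } else if (inherits(e, "hla_heterodimer")) {
      format(e$beta) == format(b)
    } else if (inherits(b, "hla_heterodimer")) {
      is_molecular2(e) && format(e) == format(b$beta)
    } else {
      is_molecular2(e) && format(e) == format(b)
    }
  }
  pair_antigen <- function(e, b) {
    # only donor entries below two-field resolution match at antigen level
    if (inherits(e, "hla_heterodimer") || is_molecular2(e)) return(FALSE)
    if (hla_locus(e) != hla_locus(b)) return(FALSE)
    length(intersect(eqv(e), eqv(b))) > 0L ||
      (!is.na(grp(e)) && !is.na(grp(b)) && grp(e) == grp(b))
  }
  pair_surrogate <- function(e, b) {
    if (!(inherits(e, "hla_heterodimer") || is_molecular2(e))) return(FALSE)
    if (hla_locus(e) != hla_locus(b)) return(FALSE)
    ec <- if (inherits(e, "hla_heterodimer")) e$beta else e
    (!is.na(grp(b)) && grp(b) == grp(ec)) ||
      length(intersect(eqv(ec), eqv(b))) > 0L
  }

  n <- length(entries)
  m <- nrow(beads)
  exact <- antigen <- surr <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      exact[i, j] <- pair_exact(entries[[i]], beads$spec[[j]])
      antigen[i, j] <- pair_antigen(entries[[i]], beads$spec[[j]])
      surr[i, j] <- pair_surrogate(entries[[i]], beads$spec[[j]])
    }
  }
  claimed <- rep(FALSE, m)
  out <- list()
  add <- function(i, mode, js) {
    out[[length(out) + 1L]] <<- data.frame(
      donor_target = format(entries[[i]]), match_mode = mode,
      mfi = max(beads$raw_mfi[js]), n_beads = length(js),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (any(exact[i, ])) {
      js <- which(exact[i, ] & positive & !claimed)
      if (length(js) > 0L) {
        claimed[js] <- TRUE
        add(i, "allele", js)
      }
    }
  }
  for (i in seq_len(n)) {
    if (!any(exact[i, ]) && any(antigen[i, ])) {
      js <- which(antigen[i, ] & positive & !claimed)
      if (length(js) > 0L) {
        claimed[js] <- TRUE
        add(i, "antigen", js)
      }
    }
  }
  for (i in seq_len(n)) {
    if (!any(exact[i, ]) && !any(antigen[i, ]) && any(surr[i, ])) {
      js <- which(surr[i, ] & positive)
      if (length(js) > 0L) add(i, "surrogate", js)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor_target = character(), match_mode = character(),
                      mfi = numeric(), n_beads = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$donor_target, res$match_mode), , drop = FALSE]
}

# random small matching instance for oracle-equivalence checks
random_instance <- function() {
  class1_beads <- c("A*01:01", "A*02:01", "A*02:02", "A*03:01", "A*23:01",
                    "A*24:02", "B*07:02", "B*08:01", "B*14:01", "B*14:02",
                    "B*18:01", "B*38:01", "B*44:02", "C*02:02", "C*05:01")
  class2_beads <- c("DRB1*01:01", "DRB1*08:01", "DRB1*11:01", "DRB1*12:01",
                    "DRB1*13:01", "DRB1*13:03", "DRB3*01:01", "DRB3*02:02",
                    "DRB4*01:01", "DQB1*05:01", "DQB1*06:02",
                    "DQA1*01:04/DQB1*05:01", "DQA1*05:01/DQB1*02:01")
  class1_donor <- c(class1_beads, "A*02:05", "B*14:02", "HLA-A*02", "A2",
                    "B65", "Cw5", "B*27:05")
  class2_donor <- c(class2_beads, "DRB1*13:02", "DRB1*13:04", "DR12", "DQ5",
                    "DR52", "DRB1*12:02")
  if (runif(1) < 0.5) {
    bead_pool <- class1_beads; donor_pool <- class1_donor
  } else {
    bead_pool <- class2_beads; donor_pool <- class2_donor
  }
  specs <- sample(bead_pool, sample(2:10, 1))
  mfis <- round(runif(length(specs), 0, 4000))
  cand <- sample(donor_pool, sample(1:6, 1))
  # respect the 2-entries-per-locus typing invariant
  loci <- vapply(cand, function(s) hla_locus(parse_hla(s)), character(1))
  keep <- unlist(lapply(split(seq_along(cand), loci),
                        function(ix) ix[seq_len(min(2L, length(ix)))]))
  donor <- donor_typing("rnd", cand[sort(keep)])
  list(donor = donor,
       panel = mk_panel(specs, mfis),
       cutoffs = cutoff_policy(runif(1, 500, 2000)))
}

compare_to_oracle <- function(inst) {
  got <- identify_dsa(inst$donor, inst$panel, inst$cutoffs,
                      include_eplet_calls = FALSE)
  got <- as.data.frame(got[, c("donor_target", "match_mode", "mfi",
                               "n_beads")])
  attr(got, "unrepresented") <- NULL
  got <- got[order(got$donor_target, got$match_mode), , drop = FALSE]
  want <- oracle_identify(inst$donor, inst$panel, inst$cutoffs)
  rownames(got) <- rownames(want) <- NULL
  identical(got, want)
}
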