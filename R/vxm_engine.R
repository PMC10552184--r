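# Virtual crossmatch engine: DSA identification, shared-eplet flags,
# FCXM/CDCXM prediction, organ risk stratification, PXM recommendation.

#' Organs supported by risk stratification
#' @format Character vector.
#' @export
VXM_ORGANS <- c("kidney", "heart", "lung", "pancreas", "kidney_pancreas",
                "kidney_liver")

#' Crossmatch prediction thresholds
#'
#' MFI thresholds and locus weights driving physical-crossmatch prediction.
#' Numeric MFI-to-crossmatch thresholds are deliberately center-specific in
#' practice; the defaults here are declared conventions consistent with the
#' worked-example outcome patterns (a 2122 MFI C-locus DSA predicting a
#' negative FCXM, a 12235 MFI class I DSA predicting a positive one) and are
#' meant to be calibrated per center.
#'
#' Locus weights down-scale MFI for loci with lower cell-surface expression:
#' HLA-C and HLA-DP default to 0.5. With `additive = TRUE` (the default) the
#' weighted MFIs of the relevant DSA are summed, reflecting the additive
#' effect multiple low-level DSA can have on a crossmatch; with `FALSE` the
#' maximum is compared instead.
#'
#' @param t_fcxm,b_fcxm,cdc Positivity thresholds (MFI) for the T-cell FCXM,
#'   B-cell FCXM and CDC crossmatch signals.
#' @param locus_weights Named multipliers in (0, 1]; unnamed loci weigh 1.
#' @param additive Sum weighted MFIs (`TRUE`) or compare the maximum.
#' @param indeterminate_band Half-width of the borderline band as a fraction
#'   of each threshold; surrogate or eplet-inferred calls landing inside it
#'   make the prediction indeterminate.
#' @return A `prediction_thresholds` object.
#' @export
prediction_thresholds <- function(t_fcxm = 3000, b_fcxm = 2000, cdc = 10000,
                                  locus_weights = c(C = 0.5, DPA1 = 0.5,
                                                    DPB1 = 0.5),
                                  additive = TRUE,
                                  indeterminate_band = 0.25) {
  stopifnot(t_fcxm > 0, b_fcxm > 0, cdc > 0,
            all(locus_weights > 0), all(locus_weights <= 1),
            indeterminate_band >= 0, indeterminate_band < 1)
  if (length(locus_weights) > 0L &&
      !all(names(locus_weights) %in% HLA_LOCI)) {
    stop("locus weight names must be HLA loci", call. = FALSE)
  }
  structure(list(t_fcxm = t_fcxm, b_fcxm = b_fcxm, cdc = cdc,
                 locus_weights = locus_weights, additive = additive,
                 indeterminate_band = indeterminate_band),
            class = "prediction_thresholds")
}

locus_weight <- function(th, locus) {
  if (locus %in% names(th$locus_weights)) th$locus_weights[[locus]] else 1
}

new_dsa_calls <- function(rows) {
  tbl <- if (length(rows) == 0L) {
    tibble::tibble(donor_target = character(), locus = character(),
                   hla_class = character(), match_mode = character(),
                   mfi = numeric(), n_beads = integer(),
                   bead_specificities = list(), bead_mfis = list(),
                   eplets = list(), note = character())
  } else {
    dplyr::bind_rows(rows)
  }
  structure(tbl, class = c("dsa_calls", class(tibble::tibble())))
}

dsa_row <- function(donor_target, locus, match_mode, beads,
                    eplets = character(), note = NA_character_) {
  tibble::tibble(
    donor_target = donor_target,
    locus = locus,
    hla_class = if (locus %in% HLA_CLASS1) "I" else "II",
    match_mode = match_mode,
    mfi = max(beads$mfi),         # conservative representative MFI
    n_beads = nrow(beads),
    bead_specificities = list(beads$specificity),
    bead_mfis = list(beads$mfi),
    eplets = list(eplets),
    note = note
  )
}

#' Identify donor-specific antibodies against a donor typing
#'
#' For each donor typing entry, in order of decreasing stringency:
#'
#' 1. *allele*: a bead carrying exactly the donor allele (both chains for a
#'    heterodimer when both are typed; a beta-chain-only comparison is
#'    accepted with a note when only one side can be compared);
#' 2. *antigen*: for donor entries given at group or serologic resolution,
#'    beads whose serologic equivalents cover the entry;
#' 3. *surrogate*: when the donor allele is absent from every panel, positive
#'    beads in the same antigen group (or sharing a serologic equivalent)
#'    stand in for the untested allele;
#' 4. *eplet_inferred*: shared-eplet reactivity patterns from
#'    [flag_shared_eplet()], reported as separate candidate calls.
#'
#' A bead represented on the panel at allele (or antigen) level but below
#' cutoff yields no call and suppresses surrogate matching for that donor
#' target. Positive beads matched at allele/antigen level support exactly one
#' call; surrogate calls may reuse beads across donor targets, as the same
#' same-group beads legitimately stand in for several untested alleles.
#' Calls are sorted by decreasing MFI (the maximum over supporting beads).
#'
#' @param donor A [donor_typing()].
#' @param panels A [sab_panel()] or list of panels (e.g. class I + class II).
#' @param cutoffs A [cutoff_policy()].
#' @param equivalence,eplets Lookup tables; packaged defaults.
#' @param include_eplet_calls Append eplet-inferred candidate calls.
#' @return A `dsa_calls` tibble; attribute `"unrepresented"` lists donor
#'   entries with zero bead representation on a supplied panel of their class.
#' @export
identify_dsa <- function(donor, panels, cutoffs = cutoff_policy(),
                         equivalence = hla_equivalence(),
                         eplets = hla_eplets(),
                         include_eplet_calls = TRUE) {
  if (!inherits(donor, "donor_typing")) {
    stop("donor must be a donor_typing object", call. = FALSE)
  }
  if (inherits(panels, "sab_panel")) panels <- list(panels)
  if (length(panels) == 0L) stop("at least one panel is required",
                                 call. = FALSE)
  beads <- dplyr::bind_rows(lapply(seq_along(panels), function(i) {
    calls <- call_positive(panels[[i]], cutoffs)
    calls$panel <- i
    calls
  }))
  classes_supplied <- unique(vapply(
    panels, function(p) p$assay_class, character(1)))

  entries <- donor$entries
  n <- length(entries)
  entry_fmt <- vapply(entries, format, character(1))
  bead_equiv <- lapply(beads$spec, serologic_equivalents,
                       equivalence = equivalence)
  bead_group <- vapply(beads$spec, function(s) {
    s <- if (inherits(s, "hla_heterodimer")) s$beta else s
    if (is.null(s$antigen) && length(s$fields) >= 1L) antigen_group(s)
    else NA_character_
  }, character(1))

  exact_idx <- vector("list", n)
  antigen_idx <- vector("list", n)
  surrogate_idx <- vector("list", n)
  for (i in seq_len(n)) {
    e <- entries[[i]]
    e_locus <- hla_locus(e)
    same_locus <- which(beads$locus == e_locus)
    if (inherits(e, "hla_heterodimer")) {
      exact_idx[[i]] <- same_locus[vapply(same_locus, function(j) {
        b <- beads$spec[[j]]
        if (inherits(b, "hla_heterodimer")) same_specificity(e, b)
        else format(e$beta) == format(b)   # beta-only bead
      }, logical(1))]
    } else if (is.null(e$antigen) && length(e$fields) == 2L) {
      exact_idx[[i]] <- same_locus[vapply(same_locus, function(j) {
        b <- beads$spec[[j]]
        if (inherits(b, "hla_heterodimer")) format(e) == format(b$beta)
        else same_specificity(e, b)
      }, logical(1))]
    } else {
      exact_idx[[i]] <- integer()
    }
    if (length(exact_idx[[i]]) == 0L) {
      if (!is.null(e$antigen) ||
          (!inherits(e, "hla_heterodimer") && length(e$fields) == 1L)) {
        # antigen/group-resolution donor entry
        e_eq <- serologic_equivalents(e, equivalence)
        e_grp <- if (is.null(e$antigen)) antigen_group(e) else NA_character_
        antigen_idx[[i]] <- same_locus[vapply(same_locus, function(j) {
          length(intersect(bead_equiv[[j]], e_eq)) > 0L ||
            (!is.na(e_grp) && !is.na(bead_group[j]) && bead_group[j] == e_grp)
        }, logical(1))]
      } else {
        antigen_idx[[i]] <- integer()
        e_cmp <- if (inherits(e, "hla_heterodimer")) e$beta else e
        e_eq <- serologic_equivalents(e_cmp, equivalence)
        e_grp <- antigen_group(e_cmp)
        surrogate_idx[[i]] <- same_locus[vapply(same_locus, function(j) {
          (!is.na(bead_group[j]) && bead_group[j] == e_grp) ||
            length(intersect(bead_equiv[[j]], e_eq)) > 0L
        }, logical(1))]
      }
    }
  }

  claimed <- rep(FALSE, nrow(beads))
  rows <- list()
  # pass 1: allele-exact matches claim positive beads
  for (i in seq_len(n)) {
    idx <- exact_idx[[i]]
    if (length(idx) == 0L) next
    pos <- idx[beads$positive[idx] & !claimed[idx]]
    if (length(pos) > 0L) {
      claimed[pos] <- TRUE
      note <- if (any(vapply(pos, function(j) {
        a <- entries[[i]]; b <- beads$spec[[j]]
        inherits(a, "hla_heterodimer") != inherits(b, "hla_heterodimer")
      }, logical(1)))) "beta_chain_only" else NA_character_
      rows[[length(rows) + 1L]] <- dsa_row(
        entry_fmt[i], hla_locus(entries[[i]]), "allele",
        beads[pos, , drop = FALSE], note = note)
    }
  }
  # pass 2: antigen-level matches claim remaining positive beads
  for (i in seq_len(n)) {
    idx <- antigen_idx[[i]]
    if (is.null(idx) || length(idx) == 0L) next
    pos <- idx[beads$positive[idx] & !claimed[idx]]
    if (length(pos) > 0L) {
      claimed[pos] <- TRUE
      rows[[length(rows) + 1L]] <- dsa_row(
        entry_fmt[i], hla_locus(entries[[i]]), "antigen",
        beads[pos, , drop = FALSE])
    }
  }
  # pass 3: surrogate beads for off-panel donor alleles (no claiming)
  for (i in seq_len(n)) {
    idx <- surrogate_idx[[i]]
    if (is.null(idx) || length(idx) == 0L) next
    pos <- idx[beads$positive[idx]]
    if (length(pos) > 0L) {
      rows[[length(rows) + 1L]] <- dsa_row(
        entry_fmt[i], hla_locus(entries[[i]]), "surrogate",
        beads[pos, , drop = FALSE])
    }
  }
  # pass 4: eplet-inferred candidates
  if (include_eplet_calls) {
    seen <- character()
    for (i in seq_len(n)) {
      flags <- flag_shared_eplet(entries[[i]], beads, eplets, equivalence)
      for (k in seq_len(nrow(flags))) {
        if (flags$eplet[k] %in% seen) next
        seen <- c(seen, flags$eplet[k])
        support <- beads[flags$bead_rows[[k]], , drop = FALSE]
        rows[[length(rows) + 1L]] <- dsa_row(
          entry_fmt[i], hla_locus(entries[[i]]), "eplet_inferred",
          support, eplets = flags$eplet[k])
      }
    }
  }

  out <- new_dsa_calls(rows)
  if (nrow(out) > 0L) {
    out <- out[order(-out$mfi, out$donor_target, out$match_mode), ]
  }
  unrepresented <- entry_fmt[vapply(seq_len(n), function(i) {
    cls <- if (hla_locus(entries[[i]]) %in% HLA_CLASS1) "I" else "II"
    cls %in% classes_supplied &&
      length(exact_idx[[i]]) == 0L &&
      length(antigen_idx[[i]] %||% integer()) == 0L &&
      length(surrogate_idx[[i]] %||% integer()) == 0L
  }, logical(1))]
  attr(out, "unrepresented") <- unrepresented
  out
}

#' Flag shared-eplet reactivity patterns
#'
#' An antibody to an eplet shared across antigens reacts with every carrier
#' bead, producing the characteristic "stacking" of many beads at similar
#' (often low) MFI. For each eplet carried by the donor specificity
#' (including its Bw4/Bw6 motif, treated as an eplet here), the eplet is
#' flagged when the panel holds at least two carrier beads - donor-directed
#' or not - and *all* of them are positive.
#'
#' @param donor_allele A parsed donor specificity or string.
#' @param panel_calls Output of [call_positive()] (columns `spec`, `mfi`,
#'   `positive` required).
#' @param eplets,equivalence Lookup tables.
#' @return Tibble with columns `eplet`, `n_beads`, `mfi_max` and list-columns
#'   `beads` (specificities) and `bead_rows` (row indices into `panel_calls`).
#' @export
flag_shared_eplet <- function(donor_allele, panel_calls,
                              eplets = hla_eplets(),
                              equivalence = hla_equivalence()) {
  if (!is_hla(donor_allele)) donor_allele <- parse_hla(donor_allele)
  donor_eps <- eplets_of(donor_allele, eplets, equivalence)
  bw <- bw_group(donor_allele, equivalence)
  if (bw != "none") donor_eps <- c(donor_eps, bw)
  empty <- tibble::tibble(eplet = character(), n_beads = integer(),
                          mfi_max = numeric(), beads = list(),
                          bead_rows = list())
  if (length(donor_eps) == 0L || nrow(panel_calls) == 0L) return(empty)

  bead_eps <- lapply(panel_calls$spec, function(s) {
    eps <- eplets_of(s, eplets, equivalence)
    b <- bw_group(s, equivalence)
    if (b != "none") eps <- c(eps, b)
    eps
  })
  out <- list()
  for (ep in donor_eps) {
    carriers <- which(vapply(bead_eps, function(x) ep %in% x, logical(1)))
    if (length(carriers) >= 2L && all(panel_calls$positive[carriers])) {
      out[[length(out) + 1L]] <- tibble::tibble(
        eplet = ep,
        n_beads = length(carriers),
        mfi_max = max(panel_calls$mfi[carriers]),
        beads = list(panel_calls$specificity[carriers]),
        bead_rows = list(carriers)
      )
    }
  }
  if (length(out) == 0L) empty else dplyr::bind_rows(out)
}

# weighted representative MFI of each call
weighted_mfi <- function(dsa, th) {
  if (nrow(dsa) == 0L) return(numeric())
  dsa$mfi * vapply(dsa$locus, function(l) locus_weight(th, l), numeric(1))
}

# aggregate signal of the calls that contribute to a cell type.
# Eplet-inferred candidates are excluded: they inform the indeterminate band
# and the PXM recommendation, not the aggregated signal.
fcxm_signal <- function(dsa, th, cell = c("t", "b")) {
  cell <- match.arg(cell)
  keep <- dsa$match_mode != "eplet_inferred"
  if (cell == "t") keep <- keep & dsa$hla_class == "I"
  d <- dsa[keep, , drop = FALSE]
  if (nrow(d) == 0L) return(0)
  w <- weighted_mfi(d, th)
  if (isTRUE(th$additive)) sum(w) else max(w)
}

in_band <- function(x, threshold, band) {
  x >= threshold * (1 - band) & x <= threshold * (1 + band)
}

# inferential calls (surrogate / eplet-inferred) landing in the borderline
# band force an indeterminate prediction for the affected cell type
borderline_inferential <- function(dsa, th, threshold, cell) {
  keep <- dsa$match_mode %in% c("surrogate", "eplet_inferred")
  if (cell == "t") keep <- keep & dsa$hla_class == "I"
  d <- dsa[keep, , drop = FALSE]
  if (nrow(d) == 0L) return(FALSE)
  any(in_band(weighted_mfi(d, th), threshold, th$indeterminate_band))
}

#' Predict the T- and B-cell flow crossmatch from DSA calls
#'
#' The effective signal per cell type is the aggregate (sum when additive,
#' else maximum) of locus-weighted MFIs over the relevant DSA: class I only
#' for T cells, class I plus class II for B cells. The prediction is positive
#' when the signal reaches the threshold; when any surrogate or
#' eplet-inferred call falls within the borderline band around the threshold
#' the prediction is indeterminate, reflecting that inferred reactivity of
#' borderline strength cannot support a firm call.
#'
#' @param dsa A `dsa_calls` tibble from [identify_dsa()].
#' @param th [prediction_thresholds()].
#' @return Named list with elements `t` and `b`, each `"positive"`,
#'   `"negative"` or `"indeterminate"`.
#' @export
predict_fcxm <- function(dsa, th = prediction_thresholds()) {
  one <- function(cell) {
    threshold <- if (cell == "t") th$t_fcxm else th$b_fcxm
    if (borderline_inferential(dsa, th, threshold, cell)) {
      return("indeterminate")
    }
    if (fcxm_signal(dsa, th, cell) >= threshold) "positive" else "negative"
  }
  list(t = one("t"), b = one("b"))
}

#' Predict the CDC crossmatch from DSA calls
#'
#' CDC positivity depends on complement fixation, which MFI alone does not
#' establish: without complement-binding information (e.g. a C1q assay) any
#' combination of DSA strong enough to predict a positive FCXM yields an
#' indeterminate CDC prediction rather than a positive one. With
#' `complement_binding = TRUE` the prediction is positive when the aggregate
#' signal reaches the CDC threshold; with `FALSE` it is negative.
#'
#' @inheritParams predict_fcxm
#' @param complement_binding `TRUE`, `FALSE`, or `NULL` when unknown.
#' @return Named list with elements `t` and `b`.
#' @export
predict_cdcxm <- function(dsa, th = prediction_thresholds(),
                          complement_binding = NULL) {
  one <- function(cell) {
    fc_threshold <- if (cell == "t") th$t_fcxm else th$b_fcxm
    signal <- fcxm_signal(dsa, th, cell)
    if (is.null(complement_binding)) {
      if (signal >= fc_threshold) "indeterminate" else "negative"
    } else if (isTRUE(complement_binding) && signal >= th$cdc) {
      "positive"
    } else {
      "negative"
    }
  }
  list(t = one("t"), b = one("b"))
}

#' Stratify transplant risk from DSA strength
#'
#' Risk is banded on the maximum locus-weighted DSA MFI (eplet-inferred
#' candidates excluded): below `bands[1]` low, below `bands[2]` moderate,
#' otherwise high. Combined kidney/liver transplants apply a configurable
#' one-band downgrade (the liver's protective effect on co-transplanted
#' organs), floored at low.
#'
#' @inheritParams predict_fcxm
#' @param organ One of [VXM_ORGANS].
#' @param bands Numeric length 2: lower edges of the moderate and high bands.
#' @param kidney_liver_downgrade Bands to downgrade for kidney/liver.
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
risk_stratify <- function(dsa, organ, th = prediction_thresholds(),
                          bands = c(1000, 5000),
                          kidney_liver_downgrade = 1L) {
  organ <- match.arg(organ, VXM_ORGANS)
  d <- dsa[dsa$match_mode != "eplet_inferred", , drop = FALSE]
  peak <- if (nrow(d) == 0L) 0 else max(weighted_mfi(d, th))
  level <- 1L + findInterval(peak, bands)   # 1 low, 2 moderate, 3 high
  if (organ == "kidney_liver") {
    level <- max(1L, level - as.integer(kidney_liver_downgrade))
  }
  c("low", "moderate", "high")[level]
}

#' Recommend a physical crossmatch
#'
#' A physical crossmatch is recommended whenever the virtual assessment rests
#' on inference or sits near a decision boundary: any surrogate
#' (off-panel-allele) or eplet-inferred DSA, any indeterminate prediction,
#' any DSA whose weighted MFI lies within the borderline band of an
#' applicable threshold, or a donor entry with zero bead representation on a
#' supplied panel of its class.
#'
#' @inheritParams predict_fcxm
#' @param predictions Named character vector/list of computed predictions
#'   (e.g. `t_fcxm`, `b_fcxm`, `t_cdcxm`, `b_cdcxm`); only computed ones are
#'   examined.
#' @param unrepresented Donor entries with no panel representation (from
#'   `attr(dsa, "unrepresented")`).
#' @param cdc_enabled Whether CDC prediction is part of the assessment; when
#'   `FALSE`, the CDC threshold is not used for the borderline check.
#' @return List with `recommend` (logical) and `reasons` (character codes:
#'   `off_panel_allele`, `shared_eplet`, `indeterminate_prediction`,
#'   `borderline_mfi`, `locus_unrepresented`).
#' @export
recommend_pxm <- function(dsa, predictions = character(),
                          th = prediction_thresholds(),
                          unrepresented = character(),
                          cdc_enabled = TRUE) {
  reasons <- character()
  if (any(dsa$match_mode == "surrogate")) {
    reasons <- c(reasons, "off_panel_allele")
  }
  if (any(dsa$match_mode == "eplet_inferred")) {
    reasons <- c(reasons, "shared_eplet")
  }
  if (any(unlist(predictions) == "indeterminate")) {
    reasons <- c(reasons, "indeterminate_prediction")
  }
  d <- dsa[dsa$match_mode != "eplet_inferred", , drop = FALSE]
  if (nrow(d) > 0L) {
    w <- weighted_mfi(d, th)
    applicable <- function(wi, cls) {
      ths <- c(th$b_fcxm, if (cls == "I") th$t_fcxm, if (cdc_enabled) th$cdc)
      any(in_band(wi, ths, th$indeterminate_band))
    }
    if (any(mapply(applicable, w, d$hla_class))) {
      reasons <- c(reasons, "borderline_mfi")
    }
  }
  if (length(unrepresented) > 0L) {
    reasons <- c(reasons, "locus_unrepresented")
  }
  list(recommend = length(reasons) > 0L, reasons = unique(reasons))
}

#' Run a full virtual crossmatch assessment
#'
#' Convenience wrapper chaining [identify_dsa()], [predict_fcxm()],
#' [predict_cdcxm()], [risk_stratify()] and [recommend_pxm()].
#'
#' @inheritParams identify_dsa
#' @param th [prediction_thresholds()].
#' @param organs Organs to stratify.
#' @param complement_binding Complement-binding information for CDC
#'   prediction, or `NULL` when unknown.
#' @param predict_cdc Include CDC prediction in the assessment.
#' @return A `vxm_result` list: `donor_id`, `dsa`, `t_fcxm`, `b_fcxm`,
#'   `t_cdcxm`, `b_cdcxm`, `risk`, `recommend_pxm`, `reasons`.
#' @examples
#' donor <- donor_typing("D1", c("DRB1*12:01", "DQA1*01:04/DQB1*05:01"))
#' panel <- sab_panel(data.frame(
#'   bead_id = c("b1", "b2"),
#'   specificity = c("DRB1*12:01", "DQA1*01:04/DQB1*05:01"),
#'   raw_mfi = c(2560, 10939)))
#' vxm_assess(donor, panel)
#' @export
vxm_assess <- function(donor, panels, cutoffs = cutoff_policy(),
                       th = prediction_thresholds(),
                       organs = VXM_ORGANS, complement_binding = NULL,
                       predict_cdc = TRUE,
                       equivalence = hla_equivalence(),
                       eplets = hla_eplets()) {
  dsa <- identify_dsa(donor, panels, cutoffs, equivalence, eplets)
  fc <- predict_fcxm(dsa, th)
  preds <- c(t_fcxm = fc$t, b_fcxm = fc$b)
  if (predict_cdc) {
    cdc <- predict_cdcxm(dsa, th, complement_binding)
    preds <- c(preds, t_cdcxm = cdc$t, b_cdcxm = cdc$b)
  } else {
    cdc <- list(t = NA_character_, b = NA_character_)
  }
  risk <- vapply(organs, function(o) risk_stratify(dsa, o, th), character(1))
  rec <- recommend_pxm(dsa, preds, th,
                       unrepresented = attr(dsa, "unrepresented"),
                       cdc_enabled = predict_cdc)
  structure(
    list(donor_id = donor$donor_id, dsa = dsa,
         t_fcxm = fc$t, b_fcxm = fc$b, t_cdcxm = cdc$t, b_cdcxm = cdc$b,
         risk = risk, recommend_pxm = rec$recommend, reasons = rec$reasons),
    class = "vxm_result"
  )
}

#' @export
print.vxm_result <- function(x, ...) {
  cat("<vxm_result> donor ", x$donor_id, "\n", sep = "")
  if (nrow(x$dsa) == 0L) {
    cat("  DSA: none\n")
  } else {
    cat("  DSA:\n")
    for (i in seq_len(nrow(x$dsa))) {
      ep <- x$dsa$eplets[[i]]
      cat(sprintf("    %-24s %-14s MFI %6.0f (%d bead%s)%s\n",
                  x$dsa$donor_target[i], x$dsa$match_mode[i], x$dsa$mfi[i],
                  x$dsa$n_beads[i], if (x$dsa$n_beads[i] > 1) "s" else "",
                  if (length(ep)) paste0(" via ", paste(ep, collapse = "+"))
                  else ""))
    }
  }
  cat("  FCXM prediction: T ", x$t_fcxm, ", B ", x$b_fcxm, "\n", sep = "")
  if (!is.na(x$t_cdcxm)) {
    cat("  CDCXM prediction: T ", x$t_cdcxm, ", B ", x$b_cdcxm, "\n", sep = "")
  }
  cat("  Risk: ", paste(names(x$risk), x$risk, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  Physical crossmatch recommended: ",
      if (x$recommend_pxm) "yes" else "no",
      if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "),
                                    "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Serialize a VXM result to JSON
#'
#' @param x A `vxm_result`.
#' @param path Output file.
#' @export
write_vxm_result <- function(x, path) {
  stopifnot(inherits(x, "vxm_result"))
  dsa <- as.data.frame(x$dsa[, c("donor_target", "locus", "hla_class",
                                 "match_mode", "mfi", "n_beads")])
  dsa$eplets <- vapply(x$dsa$eplets, paste, character(1), collapse = ",")
  out <- list(donor_id = x$donor_id, dsa = dsa,
              predictions = list(t_fcxm = x$t_fcxm, b_fcxm = x$b_fcxm,
                                 t_cdcxm = x$t_cdcxm, b_cdcxm = x$b_cdcxm),
              risk = as.list(x$risk),
              recommend_pxm = x$recommend_pxm, reasons = x$reasons)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
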