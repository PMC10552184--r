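# HLA nomenclature: parsing, serologic equivalence, Bw motifs, eplet lookup.

#' Classical HLA loci recognised by vxmkit
#'
#' Loci accepted in donor typings and bead specificities, at the resolution
#' typical of deceased-donor typing reports: the class I loci A, B and C, the
#' DR beta loci (DRB1 and the secondary DRB3/4/5 genes encoding DR52/DR53/DR51),
#' and the DQ/DP alpha and beta chains.
#'
#' @format Character vector of locus names.
#' @export
HLA_LOCI <- c("A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5",
              "DQA1", "DQB1", "DPA1", "DPB1")

HLA_CLASS1 <- c("A", "B", "C")
HLA_CLASS2 <- setdiff(HLA_LOCI, HLA_CLASS1)
ALPHA_LOCI <- c("DQA1", "DPA1")
BETA_PARTNER <- c(DQA1 = "DQB1", DPA1 = "DPB1")

.vxm_cache <- new.env(parent = emptyenv())

new_hla_allele <- function(locus, fields = integer(), antigen = NULL,
                           raw = NULL) {
  structure(
    list(locus = locus, fields = as.integer(fields), antigen = antigen,
         raw = raw %||% NA_character_),
    class = "hla_allele"
  )
}

new_hla_heterodimer <- function(alpha, beta, raw = NULL) {
  structure(list(alpha = alpha, beta = beta, raw = raw %||% NA_character_),
            class = "hla_heterodimer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an HLA allele, antigen or heterodimer string
#'
#' Accepts molecular names at one- or two-field resolution (`"A*02:05"`,
#' `"A*02"`), serologic antigen names (`"B65"`, `"DR12"`, `"Cw5"`, `"DQ5"`,
#' `"DR52"`), and slash-joined alpha/beta heterodimers
#' (`"DQA1*01:04/DQB1*05:01"`). An optional `"HLA-"` prefix is stripped.
#' Serologic names are kept at antigen resolution; matching against molecular
#' names then goes through the equivalence table (see
#' [serologic_equivalents()]).
#'
#' Null and expression-variant suffixes (N, L, Q, ...) and three/four-field
#' names are rejected: silently accepting them would corrupt donor-specific
#' antibody matching.
#'
#' @param text A single HLA name.
#' @return An object of class `hla_allele`, or `hla_heterodimer` for
#'   alpha/beta pairs.
#' @examples
#' parse_hla("A*02:05")
#' parse_hla("HLA-A*02")
#' parse_hla("B65")
#' parse_hla("DQA1*01:04/DQB1*05:01")
#' @export
parse_hla <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("HLA name must be a single non-empty string", call. = FALSE)
  }
  s <- trimws(text)
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("cannot parse heterodimer '", text,
           "': expected exactly one '/' separator", call. = FALSE)
    }
    chains <- lapply(parts, parse_hla_single, original = text)
    loci <- vapply(chains, function(a) a$locus, character(1))
    alpha_i <- which(loci %in% ALPHA_LOCI)
    beta_i <- which(loci %in% unname(BETA_PARTNER))
    if (length(alpha_i) != 1L || length(beta_i) != 1L ||
        BETA_PARTNER[[loci[alpha_i]]] != loci[beta_i]) {
      stop("invalid heterodimer pairing '", text,
           "': expected DQA1+DQB1 or DPA1+DPB1", call. = FALSE)
    }
    return(new_hla_heterodimer(chains[[alpha_i]], chains[[beta_i]], raw = s))
  }
  parse_hla_single(s, original = text)
}

parse_hla_single <- function(s, original = s) {
  s <- trimws(s)
  s <- sub("^HLA-", "", s, ignore.case = TRUE)
  if (grepl("*", s, fixed = TRUE)) {
    locus <- sub("\\*.*$", "", s)
    rest <- sub("^[^*]*\\*", "", s)
    if (!locus %in% HLA_LOCI) {
      stop("unknown HLA locus '", locus, "' in '", original, "'",
           call. = FALSE)
    }
    if (grepl("[A-Za-z]$", rest)) {
      stop("expression-variant suffix in '", original,
           "' is not supported", call. = FALSE)
    }
    fields <- strsplit(rest, ":", fixed = TRUE)[[1]]
    if (length(fields) < 1L || length(fields) > 2L ||
        !all(grepl("^[0-9]+$", fields))) {
      stop("cannot parse allele fields in '", original,
           "': expected one or two numeric fields", call. = FALSE)
    }
    return(new_hla_allele(locus, as.integer(fields), raw = s))
  }
  if (grepl(":", s, fixed = TRUE)) {
    stop("malformed allele '", original, "': missing '*' separator",
         call. = FALSE)
  }
  parse_serologic(s, original)
}

parse_serologic <- function(s, original) {
  u <- toupper(s)
  if (grepl("^BW[0-9]+$", u)) {
    stop("'", original, "' is a Bw epitope motif, not an antigen; ",
         "use bw_group() for Bw4/Bw6 assignment", call. = FALSE)
  }
  spec <- NULL
  if (grepl("^A[0-9]{1,2}$", u)) {
    spec <- list("A", paste0("A", sub("^A", "", u)))
  } else if (grepl("^B[0-9]{1,2}$", u)) {
    spec <- list("B", paste0("B", sub("^B", "", u)))
  } else if (grepl("^CW[0-9]{1,2}$", u)) {
    spec <- list("C", paste0("Cw", sub("^CW", "", u)))
  } else if (u %in% c("DR51", "DR52", "DR53")) {
    locus <- c(DR51 = "DRB5", DR52 = "DRB3", DR53 = "DRB4")[[u]]
    spec <- list(locus, u)
  } else if (grepl("^DR[0-9]{1,3}$", u)) {
    spec <- list("DRB1", u)
  } else if (grepl("^DQ[0-9]{1,2}$", u)) {
    spec <- list("DQB1", u)
  } else if (grepl("^DP[0-9]{1,2}$", u)) {
    spec <- list("DPB1", u)
  }
  if (is.null(spec)) {
    stop("cannot parse HLA name '", original, "'", call. = FALSE)
  }
  new_hla_allele(spec[[1]], integer(), antigen = spec[[2]], raw = s)
}

#' @export
format.hla_allele <- function(x, ...) {
  if (!is.null(x$antigen)) return(x$antigen)
  paste0(x$locus, "*", paste(sprintf("%02d", x$fields), collapse = ":"))
}

#' @export
format.hla_heterodimer <- function(x, ...) {
  paste0(format(x$alpha), "/", format(x$beta))
}

#' @export
print.hla_allele <- function(x, ...) {
  kind <- if (!is.null(x$antigen)) "serologic antigen"
          else if (length(x$fields) == 1L) "allele group" else "allele"
  cat("<hla ", kind, "> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.hla_heterodimer <- function(x, ...) {
  cat("<hla heterodimer> ", format(x), "\n", sep = "")
  invisible(x)
}

is_hla <- function(x) inherits(x, c("hla_allele", "hla_heterodimer"))

#' Locus and class of a parsed HLA specificity
#'
#' For heterodimers the beta chain's locus is reported, matching how
#' laboratories index DQ/DP specificities.
#'
#' @param x A parsed specificity from [parse_hla()].
#' @return `hla_locus()`: a locus name; `hla_class()`: `"I"` or `"II"`.
#' @export
hla_locus <- function(x) {
  if (inherits(x, "hla_heterodimer")) return(x$beta$locus)
  x$locus
}

#' @rdname hla_locus
#' @export
hla_class <- function(x) {
  if (hla_locus(x) %in% HLA_CLASS1) "I" else "II"
}

#' Antigen-level group key of a molecular allele
#'
#' The locus plus first field (`"A*02"` for A*02:01, A*02:02 and A*02:05).
#' All alleles in a group share the key, which is how surrogate beads are
#' selected for donor alleles missing from a panel.
#'
#' @param a An `hla_allele` with at least one field.
#' @return Group key string.
#' @examples
#' antigen_group(parse_hla("A*02:05"))
#' @export
antigen_group <- function(a) {
  if (inherits(a, "hla_heterodimer")) return(antigen_group(a$beta))
  if (!inherits(a, "hla_allele")) a <- parse_hla(a)
  if (length(a$fields) < 1L) {
    stop("antigen_group() needs a molecular allele; '", format(a),
         "' is serologic and must be resolved through the equivalence table",
         call. = FALSE)
  }
  paste0(a$locus, "*", sprintf("%02d", a$fields[1]))
}

# ---- equivalence table -----------------------------------------------------

#' Load an allele-to-antigen equivalence table
#'
#' The table maps two-field alleles to their split and broad serologic
#' antigens and records the Bw4/Bw6 motif carried by each B-locus antigen
#' (and the A-locus antigens with a Bw4 association). The packaged table
#' covers the antigens needed for the worked examples plus the common
#' serologic catalogue around them; it is a plain CSV
#' (`allele,antigen_split,antigen_broad,bw`) so laboratories can extend it.
#'
#' @param path CSV file; defaults to the packaged table.
#' @return A tibble of class `hla_equivalence`.
#' @export
hla_equivalence <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.vxm_cache$equivalence)) {
    return(.vxm_cache$equivalence)
  }
  if (default) {
    path <- system.file("extdata", "equivalence.csv", package = "vxmkit")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("allele", "antigen_split", "antigen_broad", "bw")
  if (!all(needed %in% names(df))) {
    stop("equivalence table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  df$bw[is.na(df$bw)] <- ""
  bad <- !df$bw %in% c("", "Bw4", "Bw6")
  if (any(bad)) {
    stop("invalid bw assignment: ", paste(unique(df$bw[bad]), collapse = ", "),
         call. = FALSE)
  }
  # each split antigen must map to exactly one broad
  broads <- tapply(df$antigen_broad, df$antigen_split,
                   function(x) length(unique(x)))
  if (any(broads > 1L)) {
    stop("split antigen(s) mapping to more than one broad: ",
         paste(names(broads)[broads > 1L], collapse = ", "), call. = FALSE)
  }
  out <- structure(tibble::as_tibble(df),
                   class = c("hla_equivalence", class(tibble::tibble())))
  if (default) .vxm_cache$equivalence <- out
  out
}

#' Serologic equivalents of a specificity
#'
#' Split antigen first, then the broad when one exists (`B*14:02` is the B65
#' split of the B14 broad). Heterodimers resolve through their beta chain,
#' matching antigen-level consensus reporting. A specificity absent from the
#' table yields an empty vector: the caller decides the fallback.
#'
#' @param a Parsed specificity or string.
#' @param equivalence An [hla_equivalence()] table.
#' @return Character vector of antigen names (possibly empty).
#' @examples
#' serologic_equivalents("B*14:02")
#' serologic_equivalents("DRB1*12:01")
#' @export
serologic_equivalents <- function(a, equivalence = hla_equivalence()) {
  if (!is_hla(a)) a <- parse_hla(a)
  if (inherits(a, "hla_heterodimer")) a <- a$beta
  if (!is.null(a$antigen)) {
    hit <- equivalence[equivalence$antigen_split == a$antigen, , drop = FALSE]
    if (nrow(hit) == 0L) return(a$antigen)
    return(unique(c(a$antigen, hit$antigen_broad[1])))
  }
  if (length(a$fields) < 2L) {
    # group-level input: union over the group's alleles
    key <- paste0("^", gsub("\\*", "\\\\*", antigen_group(a)), ":")
    hit <- equivalence[grepl(key, equivalence$allele), , drop = FALSE]
  } else {
    hit <- equivalence[equivalence$allele == format(a), , drop = FALSE]
  }
  if (nrow(hit) == 0L) return(character())
  unique(c(hit$antigen_split, hit$antigen_broad))
}

#' Bw4/Bw6 motif carried by a B-locus (or associated A-locus) specificity
#'
#' Every B-locus antigen carries exactly one of the mutually exclusive Bw4 and
#' Bw6 public motifs; a handful of A-locus antigens carry Bw4. Antibodies to
#' these motifs react with every carrier bead, so the motif behaves like a
#' shared eplet in reactivity analysis.
#'
#' @inheritParams serologic_equivalents
#' @return `"Bw4"`, `"Bw6"`, or `"none"` for loci without a Bw assignment.
#' @examples
#' bw_group("B*14:02")
#' bw_group("A*02:01")
#' @export
bw_group <- function(a, equivalence = hla_equivalence()) {
  if (!is_hla(a)) a <- parse_hla(a)
  if (inherits(a, "hla_heterodimer")) return("none")
  eq <- serologic_equivalents(a, equivalence)
  if (length(eq) == 0L && is.null(a$antigen)) return("none")
  hit <- equivalence[equivalence$antigen_split %in% eq |
                       equivalence$allele == format(a), , drop = FALSE]
  bw <- setdiff(unique(hit$bw), "")
  if (length(bw) == 0L) return("none")
  bw[1]
}

# ---- eplet table -----------------------------------------------------------

#' Load an eplet carrier table
#'
#' Maps eplet names to the serologic antigens (or two-field alleles) that
#' carry them. Carriage may be `confirmed` or `unverified`; unverified rows
#' record antigens where only specific, unnamed alleles carry the eplet, and
#' are excluded from [eplets_of()] but visible through
#' [eplet_carrier_status()]. Names are matched case-insensitively.
#'
#' @param path CSV file (`eplet,carrier,status`); defaults to the packaged
#'   table covering the DR-locus eplets 96HK, 11STS and 16Y.
#' @return A tibble of class `hla_eplets`.
#' @export
hla_eplets <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.vxm_cache$eplets)) return(.vxm_cache$eplets)
  if (default) {
    path <- system.file("extdata", "eplets.csv", package = "vxmkit")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("eplet", "carrier") %in% names(df))) {
    stop("eplet table must have columns eplet, carrier", call. = FALSE)
  }
  if (is.null(df$status)) df$status <- "confirmed"
  if (any(!nzchar(df$carrier))) {
    stop("eplet table has empty carrier entries", call. = FALSE)
  }
  out <- structure(tibble::as_tibble(df),
                   class = c("hla_eplets", class(tibble::tibble())))
  if (default) .vxm_cache$eplets <- out
  out
}

#' Eplets carried by a specificity
#'
#' Returns the eplets whose confirmed carrier set contains the specificity
#' itself, its antigen-level group, or any of its serologic equivalents.
#'
#' @inheritParams serologic_equivalents
#' @param eplets An [hla_eplets()] table.
#' @examples
#' eplets_of("DRB1*13:02")   # 96HK and 11STS via DR13
#' eplets_of("DRB3*01:01")   # DR52 carries neither
#' @export
eplets_of <- function(a, eplets = hla_eplets(),
                      equivalence = hla_equivalence()) {
  if (!is_hla(a)) a <- parse_hla(a)
  if (inherits(a, "hla_heterodimer")) a <- a$beta
  keys <- c(format(a), serologic_equivalents(a, equivalence))
  if (is.null(a$antigen) && length(a$fields) >= 1L) {
    keys <- c(keys, antigen_group(a))
  }
  keys <- toupper(unique(keys))
  confirmed <- eplets[eplets$status == "confirmed", , drop = FALSE]
  sort(unique(confirmed$eplet[toupper(confirmed$carrier) %in% keys]))
}

#' @rdname eplets_of
#' @param eplet An eplet name.
#' @param carrier An antigen or allele name.
#' @return `eplet_carrier_status()`: `"yes"`, `"no"`, or `"unknown"` when
#'   carriage is restricted to unnamed alleles of the antigen.
#' @export
eplet_carrier_status <- function(eplet, carrier, eplets = hla_eplets()) {
  rows <- eplets[toupper(eplets$eplet) == toupper(eplet) &
                   toupper(eplets$carrier) == toupper(carrier), , drop = FALSE]
  if (nrow(rows) == 0L) return("no")
  if (any(rows$status == "confirmed")) "yes" else "unknown"
}

# ---- donor typing ----------------------------------------------------------

#' Construct a donor HLA typing
#'
#' A donor typing is a list of parsed entries, at most two per locus
#' (heterodimers are counted under their beta-chain locus; DRB3/4/5 may be
#' absent). Mixed resolution is allowed: two-field alleles, one-field groups
#' and serologic antigens can coexist, as in deceased-donor typing reports.
#'
#' @param donor_id Identifier string.
#' @param alleles Character vector of HLA names (see [parse_hla()]).
#' @return A `donor_typing` object.
#' @examples
#' donor_typing("AC-153", c("B*14:02", "B*18:01", "DRB1*12:01"))
#' @export
donor_typing <- function(donor_id, alleles) {
  if (length(alleles) == 0L) stop("donor typing is empty", call. = FALSE)
  entries <- lapply(alleles, parse_hla)
  loci <- vapply(entries, hla_locus, character(1))
  per_locus <- table(loci)
  if (any(per_locus > 2L)) {
    stop("more than 2 entries at locus ",
         paste(names(per_locus)[per_locus > 2L], collapse = ", "),
         call. = FALSE)
  }
  structure(list(donor_id = donor_id, entries = entries, loci = loci),
            class = "donor_typing")
}

#' Read a donor typing from CSV
#'
#' Expects columns `locus` and `allele`, one row per entry; the locus column
#' is checked against the parsed allele.
#'
#' @param path CSV file.
#' @param donor_id Identifier; defaults to the file name.
#' @export
read_donor <- function(path, donor_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "allele") %in% names(df))) {
    stop("donor CSV must have columns locus, allele", call. = FALSE)
  }
  d <- donor_typing(donor_id %||% sub("\\.csv$", "", basename(path)),
                    df$allele)
  mismatch <- which(d$loci != df$locus)
  if (length(mismatch) > 0L) {
    stop("row ", mismatch[1], ": allele '", df$allele[mismatch[1]],
         "' does not belong to stated locus '", df$locus[mismatch[1]], "'",
         call. = FALSE)
  }
  d
}

#' @export
format.donor_typing <- function(x, ...) {
  paste0(x$donor_id, " [", paste(vapply(x$entries, format, character(1)),
                                 collapse = ", "), "]")
}

#' @export
print.donor_typing <- function(x, ...) {
  cat("<donor_typing> ", format(x), "\n", sep = "")
  invisible(x)
}

# exact-match comparison used by the matching engine
same_specificity <- function(a, b) {
  if (inherits(a, "hla_heterodimer") && inherits(b, "hla_heterodimer")) {
    return(format(a$alpha) == format(b$alpha) &&
             format(a$beta) == format(b$beta))
  }
  if (inherits(a, "hla_heterodimer") || inherits(b, "hla_heterodimer")) {
    return(FALSE)
  }
  format(a) == format(b)
}
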