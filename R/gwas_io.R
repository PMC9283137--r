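# GWAS summary statistics: data model, file IO, instrument selection,
# allele harmonisation.

CANONICAL_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
REQUIRED_COLS  <- c("snp", "ea", "oa", "beta", "se", "pval")
VALID_ALLELES  <- c("A", "C", "G", "T")
ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct a validated GWAS summary-statistics table
#'
#' A `summary_stats` object is a data frame with canonical columns
#' `snp, chr, pos, ea, oa, eaf, beta, se, pval, n` (one row per biallelic SNP)
#' plus trait metadata. `beta` is the additive effect per copy of the effect
#' allele `ea`; for binary traits it is a log odds ratio. Rows must satisfy:
#' unique SNP ids, single-letter A/C/G/T alleles with `ea != oa`, `se > 0`,
#' `pval` in (0, 1], and `eaf` in (0, 1) when present.
#'
#' @param records data frame holding at least the required canonical columns
#'   (`snp, ea, oa, beta, se, pval`); optional columns `chr, pos, eaf, n` are
#'   filled with `NA` when absent.
#' @param trait_label short trait name (e.g. `"EA"`, `"BMI"`, `"T2D"`).
#' @param trait_type `"continuous"` or `"binary-logodds"`.
#' @param unit free-text unit of `beta` (e.g. `"SD (4.2 years)"`, `"kg/m^2"`,
#'   `"log-odds"`).
#' @return A `summary_stats` object (data frame subclass).
#' @seealso [read_summary_stats()] for file import with per-row rejection
#'   logging, [validate_snp_records()] for the row-level checks.
#' @export
summary_stats <- function(records, trait_label,
                          trait_type = c("continuous", "binary-logodds"),
                          unit = NA_character_) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(records)) config_error("`records` must be a data frame")
  missing_cols <- setdiff(REQUIRED_COLS, names(records))
  if (length(missing_cols))
    config_error(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  for (col in setdiff(CANONICAL_COLS, names(records))) records[[col]] <- NA
  records <- records[CANONICAL_COLS]
  records$snp <- as.character(records$snp)
  records$chr <- as.character(records$chr)
  records$ea  <- toupper(as.character(records$ea))
  records$oa  <- toupper(as.character(records$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    records[[col]] <- as.numeric(records[[col]])
  chk <- validate_snp_records(records)
  if (nrow(chk$rejected))
    input_error(paste0("invalid records: ",
                       paste(unique(chk$rejected$reason), collapse = "; "),
                       " (use read_summary_stats() to filter with a log)"))
  out <- chk$records
  rownames(out) <- NULL
  structure(out,
            trait_label = trait_label, trait_type = trait_type, unit = unit,
            class = c("summary_stats", "data.frame"))
}

#' Row-level validation of SNP records
#'
#' Splits a canonical-column data frame into valid rows and rejected rows with
#' a per-row reason. Indels and multi-allelic records (allele strings other
#' than a single A/C/G/T) are rejected; of duplicated SNP ids only the first
#' occurrence is kept.
#'
#' @param records data frame with canonical columns.
#' @return list with elements `records` (valid rows) and `rejected`
#'   (data frame `snp`, `reason`).
#' @export
validate_snp_records <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(records$snp) | records$snp == "", "missing SNP id")
  flag(is.na(records$beta), "missing beta")
  flag(!(records$ea %in% VALID_ALLELES) | !(records$oa %in% VALID_ALLELES),
       "invalid alleles (indel/multi-allelic or non-ACGT)")
  flag(records$ea == records$oa, "identical alleles")
  flag(is.na(records$se) | records$se <= 0, "nonpositive SE")
  flag(is.na(records$pval) | records$pval <= 0 | records$pval > 1,
       "p-value outside (0,1]")
  flag(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1),
       "EAF outside (0,1)")
  flag(duplicated(records$snp), "duplicate SNP id")
  bad <- !is.na(reason)
  list(records  = records[!bad, , drop = FALSE],
       rejected = data.frame(snp = as.character(records$snp[bad]),
                             reason = reason[bad],
                             stringsAsFactors = FALSE))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s [%s, unit: %s], %d SNPs\n",
              attr(x, "trait_label"), attr(x, "trait_type"),
              attr(x, "unit"), nrow(x)))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

trait_label <- function(ss) attr(ss, "trait_label")
trait_type  <- function(ss) attr(ss, "trait_type")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header, renames columns to the
#' canonical scheme via `column_map`, validates rows, and returns a
#' [summary_stats()] object. Rows violating the record invariants are dropped
#' and logged (attribute `"rejected"`, plus a message).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names to source
#'   headers, e.g. `c(snp = "MarkerName", beta = "Beta", se = "SE", ...)`.
#'   Canonical names already present in the header need not be mapped.
#' @param trait_label,trait_type,unit trait metadata, see [summary_stats()].
#' @return `summary_stats` with attribute `rejected` (data frame of dropped
#'   rows and reasons).
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_label,
                               trait_type = c("continuous", "binary-logodds"),
                               unit = NA_character_) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(raw))
    if (length(miss))
      config_error(paste0("column_map refers to absent column(s): ",
                          paste(miss, collapse = ", ")))
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols))
    config_error(paste0("missing mapped column(s): ",
                        paste(missing_cols, collapse = ", ")))
  for (col in setdiff(CANONICAL_COLS, names(raw))) raw[[col]] <- NA
  raw <- raw[CANONICAL_COLS]
  raw$snp <- as.character(raw$snp)
  raw$chr <- as.character(raw$chr)
  raw$ea  <- toupper(as.character(raw$ea))
  raw$oa  <- toupper(as.character(raw$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  chk <- validate_snp_records(raw)
  if (nrow(chk$records) == 0L)
    input_error(sprintf("no valid rows in %s", path))
  if (nrow(chk$rejected))
    message(sprintf("read_summary_stats: dropped %d row(s): %s",
                    nrow(chk$rejected),
                    paste(sprintf("%s (%s)", chk$rejected$snp,
                                  chk$rejected$reason), collapse = ", ")))
  out <- summary_stats(chk$records, trait_label, trait_type, unit)
  attr(out, "rejected") <- chk$rejected
  out
}

#' Write summary statistics to a tab-delimited file
#'
#' Canonical header `snp chr pos ea oa eaf beta se pval n`; an empty record
#' set yields a header-only file. `read_summary_stats()` on the result
#' reproduces the input field-by-field.
#'
#' @param ss a [summary_stats()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path) {
  if (!inherits(ss, "summary_stats")) config_error("`ss` must be summary_stats")
  utils::write.table(as.data.frame(ss)[CANONICAL_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Pairwise LD lookup table
#'
#' Stores r-squared values for unordered SNP pairs together with the clumping
#' window in base pairs. `r2(a, a) = 1` by definition; pairs absent from the
#' table, or farther apart than `window` (when positions are known), are
#' treated as independent (`r2 = 0`).
#'
#' @param pairs either a data frame with columns `snp_a, snp_b, r2`, a square
#'   numeric matrix with SNP ids as dimnames, or `NULL` (all pairs
#'   independent).
#' @param window window in bp outside which pairs are unconditionally
#'   independent (default 1 Mb).
#' @return An `ld_info` object.
#' @export
ld_info <- function(pairs = NULL, window = 1e6) {
  assert_scalar_num(window, "window")
  tab <- numeric(0)
  if (is.matrix(pairs)) {
    ids <- rownames(pairs) %||% colnames(pairs)
    if (is.null(ids) || !identical(rownames(pairs), colnames(pairs)))
      config_error("LD matrix needs identical row/column SNP-id names")
    idx <- which(upper.tri(pairs), arr.ind = TRUE)
    pairs <- data.frame(snp_a = ids[idx[, 1]], snp_b = ids[idx[, 2]],
                        r2 = pairs[idx], stringsAsFactors = FALSE)
  }
  if (!is.null(pairs)) {
    if (!all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
      config_error("LD pairs need columns snp_a, snp_b, r2")
    if (any(pairs$r2 < 0 | pairs$r2 > 1, na.rm = TRUE))
      input_error("r2 values must lie in [0,1]")
    key <- pair_key(pairs$snp_a, pairs$snp_b)
    tab <- stats::setNames(pairs$r2, key)
    tab <- tab[!duplicated(names(tab))]
  }
  structure(list(table = tab, window = window), class = "ld_info")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read an LD table from file
#'
#' Accepts either the 3-column format (`snp_a snp_b r2`, tab-delimited with
#' header) or a square matrix with an id header column.
#'
#' @param path file path.
#' @param window clumping window in bp.
#' @return An [ld_info()] object.
#' @export
read_ld_info <- function(path, window = 1e6) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(raw))) return(ld_info(raw, window))
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  ld_info(m, window)
}

#' Look up pairwise r-squared
#' @param ld an [ld_info()] object (or `NULL`: everything independent).
#' @param a,b SNP ids (vectorised over `b`).
#' @return numeric r-squared values.
#' @export
ld_r2 <- function(ld, a, b) {
  out <- ifelse(b == a, 1, 0)
  if (!is.null(ld) && length(ld$table)) {
    hit <- ld$table[pair_key(rep_len(a, length(b)), b)]
    out <- ifelse(b == a, 1, ifelse(is.na(hit), 0, hit))
  }
  unname(out)
}

#' Select independent genome-wide significant instruments (greedy LD clumping)
#'
#' Keeps SNPs with `pval < p_threshold`, then greedily clumps in ascending
#' p-value order (ties broken by SNP id, lexicographic): the best remaining
#' SNP is retained and every unselected SNP with `r2 >= r2_threshold` within
#' `window` bp of it is pruned. Pairs with unknown positions are treated as
#' within the window; pairs absent from `ld` as independent. The default
#' thresholds (`p < 5e-8`, `r2 < 0.1`, 1 Mb) are the conventional ones; they
#' are arguments because source GWAS differ (e.g. stricter p for BMI,
#' `r2 < 0.005` within 5 Mb for television watching, 500 kb for smoking).
#'
#' @param ss a [summary_stats()] object.
#' @param p_threshold retain only `pval < p_threshold`.
#' @param ld an [ld_info()] object or `NULL`.
#' @param r2_threshold prune pairs with `r2 >= r2_threshold`.
#' @param window bp window (defaults to the `ld` object's window).
#' @return `summary_stats` of retained instruments, sorted by ascending
#'   (p-value, SNP id).
#' @export
select_instruments <- function(ss, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.1, window = NULL) {
  if (!inherits(ss, "summary_stats")) config_error("`ss` must be summary_stats")
  window <- window %||% (if (!is.null(ld)) ld$window else 1e6)
  keep <- ss[ss$pval < p_threshold, , drop = FALSE]
  if (nrow(keep) == 0L)
    input_error(sprintf("no SNP passes p < %g for trait %s",
                        p_threshold, trait_label(ss)))
  keep <- keep[order(keep$pval, keep$snp), , drop = FALSE]
  retained <- logical(nrow(keep))
  pruned <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    if (pruned[i]) next
    retained[i] <- TRUE
    if (i == nrow(keep)) break
    rest <- which(!pruned & !retained)
    rest <- rest[rest > i]
    if (!length(rest)) next
    in_window <- rep(TRUE, length(rest))
    if (!is.na(keep$pos[i])) {
      pos_ok <- !is.na(keep$pos[rest])
      same_chr <- !is.na(keep$chr[rest]) & !is.na(keep$chr[i]) &
        keep$chr[rest] == keep$chr[i]
      dist_in <- abs(keep$pos[rest] - keep$pos[i]) <= window
      # distance rule only applies when both positions (and chromosome) known
      in_window <- ifelse(pos_ok & !is.na(keep$chr[i]) & !is.na(keep$chr[rest]),
                          same_chr & dist_in, TRUE)
    }
    r2 <- ld_r2(ld, keep$snp[i], keep$snp[rest])
    pruned[rest[in_window & r2 >= r2_threshold]] <- TRUE
  }
  out <- keep[retained, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_label = trait_label(ss), trait_type = trait_type(ss),
            unit = attr(ss, "unit"), class = c("summary_stats", "data.frame"))
}

is_palindromic <- function(ea, oa) unname(ALLELE_COMPLEMENT[ea] == oa)

# classify one trait's alleles against the reference orientation:
# "keep", "flip", or a drop reason
align_action <- function(ref_ea, ref_oa, ea, oa) {
  if (ea == ref_ea && oa == ref_oa) return("keep")
  if (ea == ref_oa && oa == ref_ea) return("flip")
  cea <- ALLELE_COMPLEMENT[[ea]]; coa <- ALLELE_COMPLEMENT[[oa]]
  if (cea == ref_ea && coa == ref_oa) return("keep")
  if (cea == ref_oa && coa == ref_ea) return("flip")
  "incompatible alleles"
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns one or more exposure tables and one outcome table to the effect
#' allele of the first (reference) exposure, over the intersection of SNP ids.
#' Where a trait's alleles are swapped relative to the reference (directly or
#' on the opposite strand), its beta sign is flipped and EAF replaced by
#' `1 - EAF`. Palindromic SNPs (A/T, C/G) cannot be resolved from alleles:
#' strand is inferred from allele-frequency agreement (after alignment all
#' EAFs must fall on the same side of 0.5), and any palindromic SNP with an
#' EAF inside the closed ambiguity interval — or with a missing EAF — is
#' dropped with reason `"ambiguous palindromic"`. Irreconcilable allele pairs
#' are dropped with reason `"incompatible alleles"`.
#'
#' @param exposures a [summary_stats()] object or list of them; the first is
#'   the reference exposure.
#' @param outcome outcome [summary_stats()].
#' @param eaf_ambiguity closed interval of ambiguous allele frequencies,
#'   default `c(0.3, 0.7)`.
#' @return A `harmonised_set`: SNP-aligned effect/SE matrices for the
#'   exposures, vectors for the outcome, and a `dropped` log.
#' @export
harmonise <- function(exposures, outcome, eaf_ambiguity = c(0.3, 0.7)) {
  if (inherits(exposures, "summary_stats")) exposures <- list(exposures)
  if (!length(exposures) || !all(vapply(exposures, inherits, TRUE, "summary_stats")))
    config_error("`exposures` must be summary_stats or a list of them")
  if (!inherits(outcome, "summary_stats")) config_error("`outcome` must be summary_stats")
  if (length(eaf_ambiguity) != 2L || eaf_ambiguity[1] > eaf_ambiguity[2])
    config_error("`eaf_ambiguity` must be c(low, high) with low <= high")
  traits <- c(exposures, list(outcome))
  labels <- vapply(traits, trait_label, "")
  ids <- Reduce(intersect, lapply(traits, function(s) s$snp))
  if (!length(ids))
    overlap_error(paste0("no shared SNPs between ",
                         paste(labels, collapse = ", ")))
  rows <- lapply(traits, function(s) s[match(ids, s$snp), , drop = FALSE])
  ref <- rows[[1]]
  K <- length(exposures)
  nT <- length(traits)
  beta <- vapply(rows, function(r) r$beta, numeric(length(ids)))
  se   <- vapply(rows, function(r) r$se,   numeric(length(ids)))
  eaf  <- vapply(rows, function(r) r$eaf,  numeric(length(ids)))
  beta <- matrix(beta, ncol = nT); se <- matrix(se, ncol = nT)
  eaf <- matrix(eaf, ncol = nT)
  drop_reason <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    pal <- is_palindromic(ref$ea[i], ref$oa[i])
    if (pal) {
      fr <- eaf[i, ]
      if (anyNA(fr) ||
          any(fr >= eaf_ambiguity[1] & fr <= eaf_ambiguity[2])) {
        drop_reason[i] <- "ambiguous palindromic"
        next
      }
      # alleles identical or swapped/complemented are indistinguishable:
      # align each trait so its EAF sits on the reference side of 0.5
      for (t in 2:nT) {
        ok_alleles <- align_action(ref$ea[i], ref$oa[i],
                                   rows[[t]]$ea[i], rows[[t]]$oa[i])
        if (identical(ok_alleles, "incompatible alleles")) {
          drop_reason[i] <- "incompatible alleles"; break
        }
        if ((fr[t] > 0.5) != (fr[1] > 0.5)) {
          beta[i, t] <- -beta[i, t]
          eaf[i, t] <- 1 - eaf[i, t]
        }
      }
    } else {
      for (t in 2:nT) {
        act <- align_action(ref$ea[i], ref$oa[i],
                            rows[[t]]$ea[i], rows[[t]]$oa[i])
        if (act == "keep") next
        if (act == "flip") {
          beta[i, t] <- -beta[i, t]
          if (!is.na(eaf[i, t])) eaf[i, t] <- 1 - eaf[i, t]
        } else { drop_reason[i] <- act; break }
      }
    }
  }
  dropped <- data.frame(snp = ids[!is.na(drop_reason)],
                        reason = drop_reason[!is.na(drop_reason)],
                        stringsAsFactors = FALSE)
  ok <- is.na(drop_reason)
  if (!any(ok)) overlap_error("all shared SNPs dropped during harmonisation")
  harmonised_set(
    snp = ids[ok],
    exposure_beta = beta[ok, seq_len(K), drop = FALSE],
    exposure_se   = se[ok, seq_len(K), drop = FALSE],
    outcome_beta  = beta[ok, nT],
    outcome_se    = se[ok, nT],
    exposure_eaf  = eaf[ok, seq_len(K), drop = FALSE],
    outcome_eaf   = eaf[ok, nT],
    effect_allele = ref$ea[ok], other_allele = ref$oa[ok],
    exposures = labels[seq_len(K)], outcome = labels[nT],
    outcome_type = trait_type(outcome), dropped = dropped)
}

#' Construct a harmonised SNP-effect set directly
#'
#' Low-level constructor for the container consumed by all estimators; useful
#' for building analysis-ready sets from already-aligned effect matrices
#' (e.g. simulated data) without going through allele harmonisation.
#'
#' @param snp SNP ids.
#' @param exposure_beta,exposure_se numeric vectors (one exposure) or
#'   n-by-K matrices.
#' @param outcome_beta,outcome_se numeric vectors.
#' @param exposures exposure labels (length K).
#' @param outcome outcome label.
#' @param outcome_type `"continuous"` or `"binary-logodds"`.
#' @param exposure_eaf,outcome_eaf,effect_allele,other_allele optional.
#' @param dropped data frame log of removed SNPs.
#' @return A `harmonised_set` object.
#' @export
harmonised_set <- function(snp, exposure_beta, exposure_se,
                           outcome_beta, outcome_se,
                           exposures = NULL, outcome = "outcome",
                           outcome_type = "continuous",
                           exposure_eaf = NULL, outcome_eaf = NULL,
                           effect_allele = NULL, other_allele = NULL,
                           dropped = data.frame(snp = character(),
                                                reason = character())) {
  exposure_beta <- as.matrix(exposure_beta)
  exposure_se   <- as.matrix(exposure_se)
  n <- length(outcome_beta)
  K <- ncol(exposure_beta)
  exposures <- exposures %||% colnames(exposure_beta) %||%
    paste0("exposure", seq_len(K))
  if (n < 1L) input_error("harmonised set must contain at least one SNP")
  if (nrow(exposure_beta) != n || nrow(exposure_se) != n ||
      length(outcome_se) != n || length(snp) != n)
    input_error("harmonised set vectors must have equal length")
  if (any(exposure_se <= 0) || any(outcome_se <= 0))
    input_error("all SEs must be > 0")
  colnames(exposure_beta) <- colnames(exposure_se) <- exposures
  structure(list(snp = as.character(snp),
                 exposure_beta = exposure_beta, exposure_se = exposure_se,
                 outcome_beta = as.numeric(outcome_beta),
                 outcome_se = as.numeric(outcome_se),
                 exposure_eaf = exposure_eaf, outcome_eaf = outcome_eaf,
                 effect_allele = effect_allele, other_allele = other_allele,
                 exposures = exposures, outcome = outcome,
                 outcome_type = outcome_type, dropped = dropped),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s ~ %s | %d SNPs, %d dropped\n",
              x$outcome, paste(x$exposures, collapse = " + "),
              length(x$snp), nrow(x$dropped)))
  invisible(x)
}

n_snps <- function(h) length(h$outcome_beta)
n_exposures <- function(h) ncol(h$exposure_beta)

# subset a harmonised set by SNP index, keeping metadata
subset_harmonised <- function(h, idx) {
  harmonised_set(h$snp[idx],
                 h$exposure_beta[idx, , drop = FALSE],
                 h$exposure_se[idx, , drop = FALSE],
                 h$outcome_beta[idx], h$outcome_se[idx],
                 exposures = h$exposures, outcome = h$outcome,
                 outcome_type = h$outcome_type,
                 dropped = h$dropped)
}
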