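# Cross-structure residue pairing. Homologous proteins differ in length, so a
# one-to-one residue comparison needs a gapped global (Needleman-Wunsch)
# sequence alignment first; only aligned pairs are compared and gap columns
# are carried along explicitly so plots can show residues without a partner.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

#' Global sequence alignment as a residue correspondence map
#'
#' Needleman-Wunsch global alignment with affine gap penalties (via
#' Biostrings), returned as a per-column map between residue ordinals of the
#' two sequences. Gap columns stretch the aligned index range beyond either
#' sequence length.
#'
#' @param seq_a,seq_b One-letter amino-acid strings (see
#'   [extract_sequence()]).
#' @param sub_matrix Substitution matrix: a name from Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An `alignment_map`: tibble with columns `column` (1-based aligned
#'   position), `ord_a`, `ord_b` (0-based residue ordinals, `NA` in a gap
#'   column); attributes `n_columns`, `score`, `aligned_a`, `aligned_b`,
#'   and the parameters used.
#' @export
global_align <- function(seq_a, seq_b, sub_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop_validation("sequences must be non-empty")
  check_residue_chars <- function(s, who) {
    bad <- setdiff(strsplit(s, "")[[1]], AA_ALPHABET)
    if (length(bad) > 0L) {
      stop_validation(sprintf("invalid residue character(s) in %s: %s",
                              who, paste(unique(bad), collapse = ", ")))
    }
  }
  check_residue_chars(seq_a, "seq_a")
  check_residue_chars(seq_b, "seq_b")
  if (is.character(sub_matrix)) {
    env <- new.env()
    utils::data(list = sub_matrix, package = "Biostrings", envir = env)
    smat <- get(sub_matrix, envir = env)
  } else {
    smat <- as.matrix(sub_matrix)
  }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = smat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a_gapped <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b_gapped <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ord_a <- ifelse(a_gapped == "-", NA_integer_, cumsum(a_gapped != "-") - 1L)
  ord_b <- ifelse(b_gapped == "-", NA_integer_, cumsum(b_gapped != "-") - 1L)
  out <- tibble(column = seq_along(a_gapped), ord_a = ord_a, ord_b = ord_b)
  attr(out, "n_columns") <- length(a_gapped)
  attr(out, "score") <- Biostrings::score(aln)
  attr(out, "aligned_a") <- paste(a_gapped, collapse = "")
  attr(out, "aligned_b") <- paste(b_gapped, collapse = "")
  attr(out, "params") <- list(
    sub_matrix = if (is.character(sub_matrix)) sub_matrix else "custom",
    gap_open = gap_open, gap_extend = gap_extend
  )
  class(out) <- c("alignment_map", class(out))
  out
}

#' Aligned residue pairs of an alignment map
#' @param map An `alignment_map`.
#' @return Tibble of columns `column`, `ord_a`, `ord_b` restricted to columns
#'   where both sequences have a residue.
#' @export
alignment_pairs <- function(map) {
  stopifnot(inherits(map, "alignment_map"))
  dplyr::filter(as_tibble(map), !is.na(.data$ord_a) & !is.na(.data$ord_b))
}

#' Compare two normalised residue profiles across an alignment
#'
#' For every aligned residue pair, the absolute difference of the normalised
#' profile values; residues without an alignment partner contribute nothing
#' and appear as gap columns with `NA` difference. Both profiles must have
#' been normalised with the same method — raw profiles from different network
#' types carry different units and their direct comparison is refused.
#'
#' @param prof_a,prof_b Normalised `residue_profile`s (see
#'   [normalize_profile()]).
#' @param map An `alignment_map` between the two structures (ordinals of
#'   `prof_a` on side a).
#' @return An `aligned_comparison` tibble with columns `column`, `label_a`,
#'   `label_b`, `diff`; attribute `mean_abs_difference` is the mean over the
#'   aligned pairs only.
#' @export
compare_profiles <- function(prof_a, prof_b, map) {
  stopifnot(inherits(prof_a, "residue_profile"), inherits(prof_b, "residue_profile"),
            inherits(map, "alignment_map"))
  if (!isTRUE(attr(prof_a, "normalized")) || !isTRUE(attr(prof_b, "normalized"))) {
    stop_validation("profiles must be normalised before comparison (see normalize_profile)")
  }
  if (!identical(attr(prof_a, "norm_method"), attr(prof_b, "norm_method"))) {
    stop_validation("profiles normalised with different methods cannot be compared")
  }
  if (max(map$ord_a, na.rm = TRUE) >= nrow(prof_a) ||
      max(map$ord_b, na.rm = TRUE) >= nrow(prof_b)) {
    stop_validation("alignment map refers to residues beyond the profiles")
  }
  ra <- match(map$ord_a, prof_a$index)
  rb <- match(map$ord_b, prof_b$index)
  diff <- abs(prof_a$normalized_value[ra] - prof_b$normalized_value[rb])
  diff[is.na(map$ord_a) | is.na(map$ord_b)] <- NA_real_
  out <- tibble(
    column = map$column,
    label_a = ifelse(is.na(ra), NA_character_, prof_a$label[ra]),
    label_b = ifelse(is.na(rb), NA_character_, prof_b$label[rb]),
    diff = diff
  )
  attr(out, "mean_abs_difference") <- mean(diff[!is.na(diff)])
  attr(out, "norm_method") <- attr(prof_a, "norm_method")
  attr(out, "semantics") <- c(attr(prof_a, "semantics"), attr(prof_b, "semantics"))
  class(out) <- c("aligned_comparison", class(out))
  out
}
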