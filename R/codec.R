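# 2-bit k-mer codec: PREFIX/QM/DP decomposition of 32-base k-mers.

#' Codec parameters for the 32-base k-mer layout
#'
#' A k-mer of fixed length 32 is decomposed into a PREFIX of the first
#' \code{n} bases (its integer value is the database group id) and a SUFFIX
#' of the last 16 bases. The SUFFIX splits into a QM field (first \code{m}
#' bases, compared under seed masks tolerating one substitution) and a DP
#' field (remaining \code{16 - m} bases, compared by banded edit distance).
#' When \code{n < 16} the middle \code{16 - n} bases of the k-mer are not
#' encoded or compared at all, which grants free error tolerance there.
#'
#' Bases are packed two bits each in the fixed order A=0, C=1, G=2, T=3,
#' leftmost base most significant, so databases are portable.
#'
#' @param n PREFIX length in bases (1--16). Default 14.
#' @param m QM length in bases (1--16). Default 6.
#' @return An object of class \code{codec_params}.
#' @examples
#' codec_params(n = 10, m = 6)
#' @export
codec_params <- function(n = 14, m = 6) {
  if (!.is_count(n) || n < 1 || n > 16)
    .dk_stop("dktax_value_error", "n must be an integer in [1, 16]")
  if (!.is_count(m) || m < 1 || m > 16)
    .dk_stop("dktax_value_error", "m must be an integer in [1, 16]")
  structure(list(k = 32L, n = as.integer(n), m = as.integer(m),
                 suffix_len = 16L, dp_len = 16L - as.integer(m),
                 base_order = "ACGT"),
            class = "codec_params")
}

#' @export
print.codec_params <- function(x, ...) {
  cat(sprintf("k-mer codec: k=%d, PREFIX n=%d, QM m=%d, DP %d bases (base order %s)\n",
              x$k, x$n, x$m, x$dp_len, x$base_order))
  invisible(x)
}

#' Encode a DNA string as a 2-bit integer code
#'
#' @param seq A DNA string over A/C/G/T (case-insensitive), at most 16 bases
#'   (longer strings exceed exact double precision).
#' @return Numeric code; leftmost base most significant.
#' @seealso [decode_bases()]
#' @export
encode_bases <- function(seq) {
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len < 1 || len > 16)
    .dk_stop("dktax_value_error", "encode_bases handles 1-16 bases")
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1
  if (anyNA(codes))
    .dk_stop("dktax_ambiguous_base", "sequence contains a non-ACGT base")
  sum(codes * 4^((len - 1):0))
}

#' Decode a 2-bit integer code back to a DNA string
#'
#' @param code Numeric code as produced by [encode_bases()].
#' @param len Number of bases encoded.
#' @return DNA string of length \code{len}.
#' @export
decode_bases <- function(code, len) {
  if (!.is_count(len) || len < 1 || len > 16)
    .dk_stop("dktax_value_error", "len must be an integer in [1, 16]")
  if (!is.numeric(code) || length(code) != 1L || is.na(code) ||
      code < 0 || code >= 4^len)
    .dk_stop("dktax_value_error", "code out of range for len bases")
  cpp_decode_code(code, as.integer(len))
}

#' Encode a 32-base k-mer into its PREFIX/SUFFIX fields
#'
#' @param seq A 32-base DNA string (case-insensitive).
#' @param params A [codec_params()] object.
#' @return A list of class \code{encoded_kmer} with \code{group_id} (integer
#'   value of the first n bases), \code{suffix_code} (last 16 bases),
#'   \code{qm_code} and \code{dp_code} (the two SUFFIX slices).
#' @examples
#' encode_kmer(strrep("ACGT", 8), codec_params(n = 14, m = 6))
#' @export
encode_kmer <- function(seq, params = codec_params()) {
  stopifnot(inherits(params, "codec_params"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) != params$k)
    .dk_stop("dktax_value_error", sprintf("seq must be a single %d-base string", params$k))
  w <- cpp_encode_windows(seq, params$n)
  if (length(w$pos) == 0L)
    .dk_stop("dktax_ambiguous_base", "k-mer contains an ambiguous base")
  suffix <- w$suffix_code[1]
  structure(list(group_id = w$group_id[1],
                 suffix_code = suffix,
                 qm_code = suffix %/% 4^params$dp_len,
                 dp_code = suffix %% 4^params$dp_len),
            class = "encoded_kmer")
}

#' Decode an encoded k-mer
#'
#' The middle \code{16 - n} bases of a k-mer are not stored when
#' \code{n < 16}; they are returned as \code{"N"} placeholders.
#'
#' @param x An \code{encoded_kmer}.
#' @param params The [codec_params()] used to encode it.
#' @return A 32-character string (exact when \code{n = 16}).
#' @export
decode_kmer <- function(x, params = codec_params()) {
  stopifnot(inherits(x, "encoded_kmer"), inherits(params, "codec_params"))
  paste0(cpp_decode_code(x$group_id, params$n),
         strrep("N", 16L - params$n),
         cpp_decode_code(x$suffix_code, 16L))
}

#' Single-base wildcard seed masks for the QM field
#'
#' Mask i wildcards (zeroes) the two bits of base i of an m-base code, so
#' two QM fields differing at no more than one base compare equal under at
#' least one mask -- guaranteeing at least m - 1 equal bases.
#'
#' @param m QM length in bases (1--16).
#' @return Numeric vector of m masks, class \code{seed_masks}.
#' @examples
#' seed_masks(6)
#' @export
seed_masks <- function(m) {
  if (!.is_count(m) || m < 1 || m > 16)
    .dk_stop("dktax_value_error", "m must be an integer in [1, 16]")
  full <- 4^m - 1
  masks <- full - 3 * 4^(m - seq_len(m))
  structure(masks, m = as.integer(m), class = "seed_masks")
}

#' Quick-match two QM codes under seed masks
#'
#' @param a,b QM codes for the same m (see [encode_kmer()]).
#' @param masks A [seed_masks()] object.
#' @return \code{TRUE} iff the two m-base fields differ at no more than one
#'   base (equal, or equal under one wildcard mask).
#' @export
qm_match <- function(a, b, masks) {
  stopifnot(inherits(masks, "seed_masks"))
  m <- attr(masks, "m")
  if (any(c(a, b) < 0) || any(c(a, b) >= 4^m))
    .dk_stop("dktax_value_error", "QM code out of range for m bases")
  cpp_qm_match(a, b, m)
}

#' Banded edit distance between two short DNA strings
#'
#' Unit-cost edit distance (substitution, insertion, deletion) restricted
#' to a diagonal band. A band width of 4 bounds the frame shift at +/- 2
#' bases, matching an error budget of two indels.
#'
#' @param q,r Strings to compare; \code{abs(nchar(q) - nchar(r))} must be
#'   within the band for a finite result.
#' @param band_width Total band width in diagonals of frame shift covered
#'   (default 4, i.e. shifts in -2..2).
#' @param max_err Cost ceiling; costs above it return \code{Inf}.
#' @return The edit distance, or \code{Inf} when it exceeds \code{max_err}
#'   or the band is infeasible.
#' @examples
#' banded_edit_cost("ACGTACGTAC", "ACGTACGTAC")  # 0
#' banded_edit_cost("ACGTACGTAC", "ACGAACGTAC")  # 1
#' @export
banded_edit_cost <- function(q, r, band_width = 4, max_err = 2) {
  stopifnot(is.character(q), is.character(r), length(q) == 1L, length(r) == 1L)
  band <- as.integer(ceiling(band_width / 2))
  cost <- cpp_banded_edit_cost(toupper(q), toupper(r), band, as.integer(max_err))
  if (cost > max_err) Inf else cost
}

#' Approximately match a query fragment against a stored k-mer
#'
#' The query fragment starts at a window position of the read and supplies
#' at least the PREFIX and QM fields; up to two bases beyond the nominal
#' 32-base window may be included so that deletions in the read do not
#' starve the DP field. A match requires an exact PREFIX (same group),
#' at most one substitution in QM, and banded edit cost at most 2 in DP
#' (end gaps on the query side are free).
#'
#' @param query Query fragment (30--34 bases; shorter fragments can still
#'   match when the DP alignment absorbs the missing bases as deletions).
#' @param ref A stored k-mer: a 32-base string, an \code{encoded_kmer}, or a
#'   list with \code{group_id}, \code{suffix_code} and optionally
#'   \code{taxid}.
#' @param params A [codec_params()] object.
#' @return A list of class \code{kmer_match}: \code{matched},
#'   \code{taxid} (if the entry carries one), \code{edit_cost} (QM
#'   substitutions plus DP cost, \code{NA} when unmatched), \code{qm_subs},
#'   \code{dp_cost}.
#' @export
match_kmer <- function(query, ref, params = codec_params()) {
  stopifnot(inherits(params, "codec_params"))
  if (is.character(ref)) ref <- encode_kmer(ref, params)
  query <- toupper(query)
  res <- cpp_match_kmer(query, ref$group_id, ref$suffix_code,
                        params$n, params$m)
  matched <- res[["matched"]] == 1L
  structure(list(matched = matched,
                 taxid = if (matched && !is.null(ref$taxid)) ref$taxid else NA_integer_,
                 edit_cost = if (matched) res[["qm_subs"]] + res[["dp_cost"]] else NA_integer_,
                 qm_subs = res[["qm_subs"]],
                 dp_cost = res[["dp_cost"]]),
            class = "kmer_match")
}

#' Alignment operations of the DP-field comparison
#'
#' Diagnostic companion to [match_kmer()]: returns the operation counts of
#' a minimal-cost alignment of the query fragment against a stored k-mer,
#' split into QM substitutions and DP substitutions/insertions/deletions.
#'
#' @inheritParams match_kmer
#' @return List with \code{qm_subs}, \code{dp_cost}, \code{dp_sub},
#'   \code{dp_ins}, \code{dp_del} and \code{matched}.
#' @export
match_kmer_detail <- function(query, ref, params = codec_params()) {
  stopifnot(inherits(params, "codec_params"))
  if (is.character(ref)) ref <- encode_kmer(ref, params)
  query <- toupper(query)
  base <- match_kmer(query, ref, params)
  qstart <- 16L + params$m
  qstop <- min(nchar(query), params$k + 2L)
  qdp <- if (qstop >= qstart + 1L) substr(query, qstart + 1L, qstop) else ""
  rdp <- cpp_decode_code(ref$suffix_code %% 4^params$dp_len, params$dp_len)
  ops <- cpp_align_ops(qdp, rdp, TRUE)
  list(matched = base$matched, qm_subs = base$qm_subs,
       dp_cost = ops[["cost"]], dp_sub = ops[["nsub"]],
       dp_ins = ops[["nins"]], dp_del = ops[["ndel"]])
}
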