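# Internal helpers: classed conditions, sequence utilities, FASTA/FASTQ IO.

.dk_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "dktax_error", "error", "condition"),
                 list(message = msg, call = call)))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

# first whitespace-delimited token of a FASTA/FASTQ header
.first_token <- function(x) sub("\\s.*$", "", x)

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Accept a named character vector, DNAStringSet, or FASTA/FASTQ path(s);
# return an uppercase named character vector keyed by the first header token.
.as_seq_vector <- function(x, format = NULL) {
  if (is.character(x) && length(x) >= 1L && all(file.exists(x))) {
    sets <- lapply(x, function(f) {
      fmt <- if (is.null(format)) .guess_format(f) else format
      Biostrings::readDNAStringSet(f, format = fmt)
    })
    x <- do.call(c, sets)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- .first_token(names(x))
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out)) && length(out))
      names(out) <- paste0("seq", seq_along(out))
  } else {
    .dk_stop("dktax_format_error",
             "sequences must be a character vector, DNAStringSet or file path")
  }
  toupper(out)
}

.guess_format <- function(path) {
  p <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
  if (grepl("\\.(fq|fastq)$", p, ignore.case = TRUE)) "fastq" else "fasta"
}

# unsigned 32-bit little-endian binary IO (R has no native unsigned int)
.write_u32 <- function(x, con) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0) || any(x >= 2^32))
    .dk_stop("dktax_format_error", "value out of unsigned 32-bit range")
  hi <- x >= 2^31
  x[hi] <- x[hi] - 2^32
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

.read_u32 <- function(con, n) {
  v <- as.numeric(readBin(con, "integer", n = n, size = 4L, endian = "little"))
  neg <- v < 0
  v[neg] <- v[neg] + 2^32
  v
}
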