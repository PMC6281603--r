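# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Check that `df` carries the named columns; `what` names the offending input
# in the error message.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Coerce genome input (file path, named character vector or DNAStringSet)
# to a named DNAStringSet.
as_dna_stringset <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    seqs <- sequences
  } else if (is.character(sequences) && length(sequences) == 1 &&
             file.exists(sequences)) {
    seqs <- Biostrings::readDNAStringSet(sequences)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      stop("character genome input must be named by chromosome", call. = FALSE)
    }
    seqs <- Biostrings::DNAStringSet(sequences)
  } else {
    stop("unsupported genome input; give a FASTA path, named character ",
         "vector or DNAStringSet", call. = FALSE)
  }
  if (length(seqs) == 0) {
    stop("genome contains no sequences", call. = FALSE)
  }
  seqs
}
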