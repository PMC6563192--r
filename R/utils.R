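# Internal helpers shared across modules.

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ltrcis_error_input")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ltrcis_error_format")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ltrcis_error_config")
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL uses (and advances) the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

DNA_BASES_ <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES_, n, replace = TRUE, prob = p), collapse = "")
}

check_genome_tbl <- function(genome, arg = "genome") {
  if (!is.data.frame(genome) ||
      !all(c("scaffold_id", "sequence") %in% names(genome))) {
    stop_input("`%s` must be a data frame with columns scaffold_id and sequence",
               arg)
  }
  if (anyDuplicated(genome$scaffold_id)) {
    stop_format("duplicate scaffold ids in `%s`", arg)
  }
  invisible(genome)
}

scaffold_seq <- function(genome, scaffold_id) {
  i <- match(scaffold_id, genome$scaffold_id)
  if (is.na(i)) stop_input("scaffold '%s' not found in genome", scaffold_id)
  genome$sequence[[i]]
}

# comma-joined list helper used for domain columns
join_names <- function(x) {
  if (length(x) == 0) NA_character_ else paste(x, collapse = ",")
}
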