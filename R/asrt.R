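#' ASRT stimulus sequences
#'
#' The Alternating Serial Reaction Time (ASRT) task presents stimuli at four
#' locations, coded `1..4`. Each block starts with a handful of warm-up trials
#' drawn uniformly at random, followed by repetitions of an 8-element
#' alternating unit in which a deterministic 4-element pattern alternates with
#' uniformly random trials (e.g. `2r4r3r1r`). The pattern restarts at the same
#' phase in every block.
#'
#' @name asrt
NULL

STIM_ALPHABET <- 1:4

#' Construct a 4-element ASRT pattern
#'
#' @param elements integer vector of length 4; a permutation of `1:4`.
#' @return An object of class `asrt_pattern`.
#' @examples
#' asrt_pattern(c(2, 4, 3, 1))
#' @export
asrt_pattern <- function(elements) {
  elements <- as.integer(elements)
  if (length(elements) != 4L || !setequal(elements, STIM_ALPHABET)) {
    stop("pattern must be a permutation of 1:4", call. = FALSE)
  }
  structure(list(elements = elements), class = "asrt_pattern")
}

#' @export
print.asrt_pattern <- function(x, ...) {
  cat("ASRT pattern:", paste(x$elements, collapse = "-"), "\n")
  invisible(x)
}

#' Canonical rotation of a pattern
#'
#' Rotates a pattern so that its smallest element comes first; two patterns
#' are equivalent as ASRT designs iff they share this canonical form, because
#' the sequence is cyclic and only the phase anchor differs.
#'
#' @param pattern an [asrt_pattern].
#' @return An `asrt_pattern`, the canonical representative.
#' @export
canonical_rotation <- function(pattern) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  e <- pattern$elements
  k <- which.min(e)
  asrt_pattern(e[((seq_len(4) + k - 2L) %% 4L) + 1L])
}

#' All canonical ASRT patterns
#'
#' Enumerates the six cyclic-rotation equivalence classes of the 24
#' permutations of `1:4`; one class per usable ASRT design.
#'
#' @return A list of six `asrt_pattern` objects, each a canonical
#'   representative starting with stimulus 1.
#' @export
canonical_patterns <- function() {
  perms <- permutations4()
  canon <- lapply(perms, function(p) canonical_rotation(asrt_pattern(p)))
  keys <- vapply(canon, function(p) paste(p$elements, collapse = ""), "")
  canon[!duplicated(keys)]
}

# all 24 permutations of 1:4, enumerated recursively
permutations4 <- function() {
  perm_rec <- function(rest) {
    if (length(rest) == 1L) return(list(rest))
    out <- list()
    for (i in seq_along(rest)) {
      for (tail in perm_rec(rest[-i])) out[[length(out) + 1L]] <- c(rest[i], tail)
    }
    out
  }
  perm_rec(1:4)
}

#' Successor of a stimulus in the pattern cycle
#'
#' @param stimulus stimulus identity in `1:4` (vectorized).
#' @param pattern an [asrt_pattern].
#' @return For each input, the pattern element that follows it in the cycle.
#' @export
pattern_successor <- function(stimulus, pattern) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  succ <- integer(4)
  e <- pattern$elements
  succ[e] <- e[c(2:4, 1L)]
  succ[stimulus]
}

#' Generate one ASRT session
#'
#' Each block consists of `block_warmup` uniformly random warm-up trials
#' followed by `pattern_repeats` repetitions of the 8-element alternating
#' unit (pattern trial, random trial, ...). With the defaults a block is
#' 5 + 8 * 10 = 85 trials, the standard design.
#'
#' @param pattern an [asrt_pattern].
#' @param n_blocks number of blocks (default 25, one standard session).
#' @param block_warmup warm-up trials per block (default 5).
#' @param pattern_repeats repetitions of the 8-element unit per block
#'   (default 10).
#' @param seed integer seed; generation is reproducible given the seed.
#' @return An object of class `asrt_sequence`: a list with `trials` (a
#'   data.frame with columns `block`, `trial` (1-based within block),
#'   `trial_global`, `stimulus`, `trial_type` in `warmup|pattern|random`,
#'   `pattern_phase` (1..4 for pattern trials, `NA` otherwise)), `pattern`,
#'   `n_blocks` and `block_length`.
#' @export
generate_session <- function(pattern, n_blocks = 25L, block_warmup = 5L,
                             pattern_repeats = 10L, seed = NULL) {
  stopifnot(inherits(pattern, "asrt_pattern"))
  n_blocks <- as.integer(n_blocks)
  block_warmup <- as.integer(block_warmup)
  pattern_repeats <- as.integer(pattern_repeats)
  if (n_blocks < 1L || block_warmup < 0L || pattern_repeats < 1L) {
    stop("n_blocks and pattern_repeats must be >= 1, block_warmup >= 0",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  block_len <- block_warmup + 8L * pattern_repeats
  blocks <- lapply(seq_len(n_blocks), function(b) {
    one_block(pattern, block_warmup, pattern_repeats, b)
  })
  trials <- do.call(rbind, blocks)
  trials$trial_global <- seq_len(nrow(trials))
  structure(list(trials = trials, pattern = pattern, n_blocks = n_blocks,
                 block_length = block_len),
            class = "asrt_sequence")
}

one_block <- function(pattern, block_warmup, pattern_repeats, block_id) {
  phases <- rep(1:4, length.out = 4L * pattern_repeats)
  n_alt <- 8L * pattern_repeats
  stim <- integer(block_warmup + n_alt)
  type <- character(block_warmup + n_alt)
  phase <- rep(NA_integer_, block_warmup + n_alt)
  if (block_warmup > 0L) {
    stim[seq_len(block_warmup)] <- sample(STIM_ALPHABET, block_warmup,
                                          replace = TRUE)
    type[seq_len(block_warmup)] <- "warmup"
  }
  idx <- block_warmup + seq_len(n_alt)
  odd <- idx[seq(1L, n_alt, by = 2L)]   # pattern trials
  even <- idx[seq(2L, n_alt, by = 2L)]  # random trials
  stim[odd] <- pattern$elements[phases]
  phase[odd] <- phases
  type[odd] <- "pattern"
  stim[even] <- sample(STIM_ALPHABET, length(even), replace = TRUE)
  type[even] <- "random"
  data.frame(block = block_id, trial = seq_along(stim), trial_global = NA_integer_,
             stimulus = stim, trial_type = type, pattern_phase = phase)
}

#' @export
print.asrt_sequence <- function(x, ...) {
  cat(sprintf("ASRT sequence: %d blocks x %d trials, pattern %s\n",
              x$n_blocks, x$block_length,
              paste(x$pattern$elements, collapse = "-")))
  invisible(x)
}

#' @export
as.data.frame.asrt_sequence <- function(x, ...) x$trials

#' Number of trials in a sequence
#' @param seq an `asrt_sequence`.
#' @return integer trial count.
#' @export
n_trials <- function(seq) nrow(seq$trials)

#' Label trials as high or low probability triplets
#'
#' A trial is a `high` triplet ending if its stimulus equals the pattern
#' successor of the stimulus two trials back (within the same block); `low`
#' otherwise. The first two trials of every block are `undefined` because no
#' two-back context exists within the block.
#'
#' @param seq an `asrt_sequence`.
#' @param pattern pattern to use; defaults to the sequence's own.
#' @return Character vector, one of `"high"`, `"low"`, `"undefined"` per trial.
#' @export
label_triplets <- function(seq, pattern = seq$pattern) {
  tr <- seq$trials
  lab <- rep("undefined", nrow(tr))
  two_back <- c(NA_integer_, NA_integer_, tr$stimulus[seq_len(nrow(tr) - 2L)])
  same_block <- c(FALSE, FALSE,
                  tr$block[seq_len(nrow(tr) - 2L)] == tr$block[-(1:2)])
  defined <- tr$trial > 2L & same_block
  succ <- pattern_successor(ifelse(is.na(two_back), 1L, two_back), pattern)
  lab[defined] <- ifelse(tr$stimulus[defined] == succ[defined], "high", "low")
  lab
}

#' Generate an interference session alternating two patterns
#'
#' Emulates a design in which the familiar pattern and an interfering pattern
#' alternate in segments of `blocks_per_switch` blocks: blocks 1..5 use
#' `pattern_a`, 6..10 `pattern_b`, and so on.
#'
#' @param pattern_a,pattern_b two [asrt_pattern]s from different rotation
#'   classes.
#' @param blocks_per_switch segment length in blocks (default 5).
#' @param n_blocks total blocks (default 20).
#' @param block_warmup,pattern_repeats as in [generate_session()].
#' @param seed integer seed.
#' @return An `asrt_sequence` whose `trials` carry an extra column
#'   `pattern_id` (`"a"` or `"b"`); `pattern` holds `pattern_a`.
#' @export
generate_interference_design <- function(pattern_a, pattern_b,
                                         blocks_per_switch = 5L,
                                         n_blocks = 20L,
                                         block_warmup = 5L,
                                         pattern_repeats = 10L,
                                         seed = NULL) {
  stopifnot(inherits(pattern_a, "asrt_pattern"),
            inherits(pattern_b, "asrt_pattern"))
  ca <- paste(canonical_rotation(pattern_a)$elements, collapse = "")
  cb <- paste(canonical_rotation(pattern_b)$elements, collapse = "")
  if (ca == cb) {
    stop("pattern_a and pattern_b are in the same rotation class",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  segment <- ((seq_len(n_blocks) - 1L) %/% blocks_per_switch) %% 2L
  blocks <- lapply(seq_len(n_blocks), function(b) {
    pat <- if (segment[b] == 0L) pattern_a else pattern_b
    out <- one_block(pat, block_warmup, pattern_repeats, b)
    out$pattern_id <- if (segment[b] == 0L) "a" else "b"
    out
  })
  trials <- do.call(rbind, blocks)
  trials$trial_global <- seq_len(nrow(trials))
  structure(list(trials = trials, pattern = pattern_a, n_blocks = n_blocks,
                 block_length = block_warmup + 8L * pattern_repeats),
            class = "asrt_sequence")
}

#' Restrict a sequence to a set of blocks
#'
#' @param seq an `asrt_sequence`.
#' @param blocks integer vector of block ids to keep.
#' @return An `asrt_sequence` with only those blocks (original block ids and
#'   global trial indices kept).
#' @export
subset_blocks <- function(seq, blocks) {
  keep <- seq$trials$block %in% blocks
  out <- seq
  out$trials <- seq$trials[keep, , drop = FALSE]
  out$n_blocks <- length(unique(out$trials$block))
  out
}
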