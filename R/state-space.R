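# Enumeration of the Stick Contest state space.
#
# A world is an (unordered-with-multiplicity) draw of 5 integer stick lengths.
# All exact listener/speaker computations run over the collapsed multiset table
# with multiplicity weights, which agrees with brute-force enumeration of the
# 9^5 ordered tuples but is ~50x smaller (1,287 rows for lengths 1..9).

.ss_cache <- new.env(parent = emptyenv())

#' Enumerate the Stick Contest state space
#'
#' Builds (and caches) the exact enumeration of all worlds of
#' `n_sticks` sticks with integer lengths drawn i.i.d. uniformly from
#' `lengths`, collapsed to multisets with multiplicity weights. Each world is
#' classified by its verdict: `"longer"` if its mean exceeds the midpoint of
#' the length range, `"shorter"` if below, `"tie"` if exactly at the midpoint.
#'
#' @param lengths Integer vector of admissible stick lengths (default `1:9`,
#'   the range used in the behavioral task; the simulation figures use `1:10`).
#' @param n_sticks Number of hidden sticks per world (default 5).
#' @return A list with components `lengths`, `midpoint`, `counts` (worlds x
#'   lengths count matrix), `mult` (number of ordered tuples realizing each
#'   multiset), `verdict` (factor), and `l0_longer` (literal-listener belief
#'   in "longer" for each revealed length, ties excluded).
#' @export
#' @examples
#' ss <- stick_state_space()
#' nrow(ss$counts)      # 1287 multisets
#' sum(ss$mult)         # 9^5 ordered worlds
stick_state_space <- function(lengths = 1:9, n_sticks = 5L) {
  lengths <- sort(unique(as.integer(lengths)))
  stopifnot(length(lengths) >= 2L, n_sticks >= 1L)
  key <- paste0(paste(lengths, collapse = ","), "|", n_sticks)
  if (!is.null(.ss_cache[[key]])) return(.ss_cache[[key]])

  nl <- length(lengths)
  # nondecreasing n_sticks-tuples over nl symbols via the combination bijection
  idx <- utils::combn(nl + n_sticks - 1L, n_sticks) - (seq_len(n_sticks) - 1L)
  counts <- t(apply(idx, 2L, function(j) tabulate(j, nbins = nl)))
  colnames(counts) <- lengths
  mult <- factorial(n_sticks) / apply(counts, 1L, function(cc) prod(factorial(cc)))
  midpoint <- (min(lengths) + max(lengths)) / 2
  mn <- as.vector(counts %*% lengths) / n_sticks
  verdict <- factor(ifelse(mn > midpoint, "longer",
                    ifelse(mn < midpoint, "shorter", "tie")),
                    levels = c("longer", "shorter", "tie"))

  # literal listener: revealed stick u + (n_sticks - 1) iid uniform completions
  # <=> world weight proportional to mult * count(u); ties renormalized away
  gl <- verdict == "longer"
  gs <- verdict == "shorter"
  wl <- as.vector(mult[gl] %*% counts[gl, , drop = FALSE])
  ws <- as.vector(mult[gs] %*% counts[gs, , drop = FALSE])
  l0 <- wl / (wl + ws)
  names(l0) <- lengths

  ss <- list(lengths = lengths, n_sticks = n_sticks, midpoint = midpoint,
             counts = counts, mult = mult, verdict = verdict, l0_longer = l0)
  .ss_cache[[key]] <- ss
  ss
}

#' Enumerate all worlds with their prior weights
#'
#' Returns the full state space as a data frame: one row per multiset world,
#' its multiplicity under the i.i.d.-uniform prior over ordered tuples, its
#' normalized prior weight, and its verdict. Deterministic (lexicographic)
#' ordering.
#'
#' @inheritParams stick_state_space
#' @return A data frame with columns `w1..w5` (sorted stick lengths),
#'   `weight` (prior mass, summing to 1), and `verdict`.
#' @export
enumerate_worlds <- function(lengths = 1:9, n_sticks = 5L) {
  ss <- stick_state_space(lengths, n_sticks)
  sticks <- t(apply(ss$counts, 1L, function(cc) rep(ss$lengths, cc)))
  colnames(sticks) <- paste0("w", seq_len(n_sticks))
  out <- data.frame(sticks, weight = ss$mult / sum(ss$mult),
                    verdict = ss$verdict)
  out
}

#' Verdict of a world
#'
#' The judge's target proposition: is the average stick length longer than the
#' midpoint of the length range?
#'
#' @param world Integer vector of 5 stick lengths.
#' @inheritParams stick_state_space
#' @return `"longer"`, `"shorter"`, or `"tie"`.
#' @export
#' @examples
#' verdict_of(c(2, 4, 7, 8, 9))  # "longer" (mean 6)
verdict_of <- function(world, lengths = 1:9) {
  world <- check_world(world, lengths)
  midpoint <- (min(lengths) + max(lengths)) / 2
  m <- mean(world)
  if (m > midpoint) "longer" else if (m < midpoint) "shorter" else "tie"
}

check_world <- function(world, lengths = 1:9) {
  world <- as.integer(world)
  if (length(world) != 5L)
    stop("a world consists of exactly 5 sticks", call. = FALSE)
  if (!all(world %in% lengths))
    stop("stick lengths must lie in {", paste(range(lengths), collapse = "..."),
         "}", call. = FALSE)
  world
}

check_utterance <- function(u, lengths = 1:9) {
  u <- as.integer(u)
  if (length(u) != 1L || !u %in% lengths)
    stop("utterance must be a single stick length in {",
         paste(range(lengths), collapse = "..."), "}", call. = FALSE)
  u
}

check_agenda <- function(agenda) {
  match.arg(agenda, c("longer", "shorter"))
}
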