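#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
NULL

# Threat states in increasing order of threat; strategies index signal levels
# by these states.
threat_states <- function() c("resting", "approached", "attacked")

signal_labels <- function() c("N", "L", "H")

#' Numeric intensities of the three discrete signal levels
#'
#' Prey signals take one of three discrete levels: none (`N`), low (`L`) and
#' high (`H`). `N` is always 0 (a silent prey cannot increase its own
#' detectability); `L` and `H` are configurable, with defaults 0.3 and 1.
#'
#' @param intensity_L,intensity_H Intensities of the low and high level,
#'   fractions in `[0, 1]` with `intensity_L <= intensity_H`.
#' @return Named numeric vector with entries `N`, `L`, `H`.
#' @examples
#' signal_levels()
#' signal_levels(0.5, 0.9)
#' @export
signal_levels <- function(intensity_L = 0.3, intensity_H = 1) {
  stopifnot(
    is.numeric(intensity_L), is.numeric(intensity_H),
    intensity_L >= 0, intensity_H <= 1, intensity_L <= intensity_H
  )
  c(N = 0, L = intensity_L, H = intensity_H)
}

#' Parse three-letter strategy codes
#'
#' A prey behavioral strategy is written as three signal-level letters, one
#' per threat state in the order resting, approached, attacked. `NHH` is a
#' pre-attack switcher (silent at rest, full signal once approached), `NNH` a
#' post-attack switcher, `HHH` a permanent strong signal.
#'
#' @param code Character vector of 3-letter codes over the alphabet
#'   `N`, `L`, `H` (case-insensitive; canonicalized to upper case).
#' @return A tibble with one row per code and columns `code`, `resting`,
#'   `approached`, `attacked` (the per-state level labels).
#' @examples
#' parse_strategy("NHH")
#' parse_strategy(c("nnh", "LLL"))
#' @export
parse_strategy <- function(code) {
  stopifnot(is.character(code))
  up <- toupper(code)
  bad_len <- nchar(up) != 3L
  if (any(bad_len)) {
    abort(sprintf(
      "Invalid strategy code '%s': must be exactly 3 letters.",
      code[bad_len][1]
    ), class = "aposwitch_invalid_strategy")
  }
  chars <- matrix(unlist(strsplit(up, "", fixed = TRUE)), ncol = 3, byrow = TRUE)
  ok <- chars %in% signal_labels()
  if (!all(ok)) {
    offending <- chars[!ok][1]
    abort(sprintf(
      "Invalid strategy code '%s': character '%s' is not one of N, L, H.",
      code[which(!matrixStats_rowAll(matrix(ok, ncol = 3)))[1]], offending
    ), class = "aposwitch_invalid_strategy")
  }
  tibble(
    code = up,
    resting = chars[, 1],
    approached = chars[, 2],
    attacked = chars[, 3]
  )
}

# all(x) by row for a logical matrix, without extra deps
matrixStats_rowAll <- function(m) rowSums(m) == ncol(m)

#' Signal intensity a strategy shows in a given threat state
#'
#' @param code Character vector of strategy codes (recycled against `state`).
#' @param state Character vector of threat states (`"resting"`,
#'   `"approached"`, `"attacked"`).
#' @param levels Named intensity map as returned by [signal_levels()].
#' @return Numeric vector of intensities in `[0, 1]`.
#' @examples
#' intensity_for_state("NNH", "attacked")
#' intensity_for_state("LLL", "approached")
#' @export
intensity_for_state <- function(code, state, levels = signal_levels()) {
  state <- match.arg(state, threat_states(), several.ok = TRUE)
  parsed <- parse_strategy(code)
  n <- max(nrow(parsed), length(state))
  idx_code <- rep_len(seq_len(nrow(parsed)), n)
  idx_state <- rep_len(state, n)
  labels <- as.matrix(parsed[idx_code, threat_states()])
  lab <- labels[cbind(seq_len(n), match(idx_state, threat_states()))]
  unname(levels[lab])
}

#' Is a strategy switchable?
#'
#' A strategy is switchable when its three level labels are not all the same;
#' only switchable prey carry the switching apparatus and pay the
#' switchability maintenance cost.
#'
#' @inheritParams intensity_for_state
#' @return Logical vector.
#' @examples
#' is_switchable(c("NNN", "HHH", "NNH"))
#' @export
is_switchable <- function(code) {
  p <- parse_strategy(code)
  !(p$resting == p$approached & p$approached == p$attacked)
}

#' Enumerate the full strategy space
#'
#' All \eqn{3^3 = 27} assignments of a signal level to each threat state, in
#' lexicographic order with N < L < H (so the first strategy is `NNN` and the
#' last `HHH`).
#'
#' @return A 27-row tibble as returned by [parse_strategy()].
#' @examples
#' enumerate_strategies()
#' @export
enumerate_strategies <- function() {
  lv <- signal_labels()
  grid <- expand.grid(
    attacked = lv, approached = lv, resting = lv,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("resting", "approached", "attacked")]
  # expand.grid varies the first factor fastest; reorder so the resting
  # letter is the slowest digit -> true lexicographic order
  ord <- order(
    match(grid$resting, lv), match(grid$approached, lv),
    match(grid$attacked, lv)
  )
  grid <- grid[ord, ]
  tibble(
    code = paste0(grid$resting, grid$approached, grid$attacked),
    resting = grid$resting,
    approached = grid$approached,
    attacked = grid$attacked
  )
}

#' Restrict a strategy set to the admissible strategies
#'
#' Two admissibility constraints reduce the 27-strategy space to nine:
#' the signal level must be non-decreasing along the threat order
#' resting -> approached -> attacked, and it may change at most once along
#' that sequence (a single switching opportunity). The surviving set is
#' NNN, NNL, NNH, NLL, NHH, LLL, LLH, LHH, HHH.
#'
#' @param strategies A strategy tibble (e.g. from [enumerate_strategies()])
#'   or a character vector of codes.
#' @param monotone Require non-decreasing intensity along the threat order.
#' @param max_switches Maximum number of level changes along the sequence.
#' @return A tibble of the retained strategies, in input order.
#' @examples
#' filter_allowed(enumerate_strategies())
#' @export
filter_allowed <- function(strategies, monotone = TRUE, max_switches = 1L) {
  if (is.character(strategies)) strategies <- parse_strategy(strategies)
  lv <- signal_labels()
  r <- match(strategies$resting, lv)
  a <- match(strategies$approached, lv)
  k <- match(strategies$attacked, lv)
  keep <- rep(TRUE, nrow(strategies))
  if (monotone) keep <- keep & (r <= a) & (a <= k)
  n_changes <- (r != a) + (a != k)
  keep <- keep & (n_changes <= max_switches)
  strategies[keep, ]
}

#' Default admissible strategy codes
#'
#' @return Character vector of the nine default strategy codes.
#' @examples
#' default_strategies()
#' @export
default_strategies <- function() filter_allowed(enumerate_strategies())$code
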