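#' Disease state space
#'
#' The three-state space used throughout the package: normal cognition
#' (`NC`), amnestic mild cognitive impairment (`aMCI`) and Alzheimer's
#' disease (`AD`).  AD is absorbing: once entered it is never left, so the
#' corresponding row of any rate matrix is identically zero.
#'
#' @return A named integer vector `c(NC = 1, aMCI = 2, AD = 3)` with an
#'   `absorbing` attribute naming the absorbing state.
#' @export
#' @examples
#' ad_states()
ad_states <- function() {
  s <- c(NC = 1L, aMCI = 2L, AD = 3L)
  attr(s, "absorbing") <- "AD"
  s
}

#' Allowed-transition structure
#'
#' Defines which instantaneous transitions carry a positive intensity.  The
#' default structure is NC -> aMCI, aMCI -> NC and aMCI -> AD: direct
#' NC -> AD conversion is excluded (clinically, conversion passes through
#' MCI, and panel cohorts rarely support estimating a direct rate), and AD
#' has no exit transitions.
#'
#' @param transitions character vector of `"from->to"` labels using the
#'   state names of [ad_states()].
#' @return An object of class `transition_structure`: a logical 3 x 3
#'   matrix, `TRUE` where the row-state -> column-state transition is
#'   allowed.
#' @export
#' @examples
#' transition_structure()
transition_structure <- function(transitions = c("NC->aMCI", "aMCI->NC", "aMCI->AD")) {
  states <- ad_states()
  m <- matrix(FALSE, 3L, 3L, dimnames = list(names(states), names(states)))
  for (tr in transitions) {
    parts <- strsplit(tr, "->", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(parts %in% names(states)))
      stop("malformed transition label: ", tr)
    if (parts[1L] == parts[2L]) stop("self-transition not allowed: ", tr)
    if (parts[1L] == attr(states, "absorbing"))
      stop("no transition may leave the absorbing state: ", tr)
    m[parts[1L], parts[2L]] <- TRUE
  }
  structure(m, class = c("transition_structure", "matrix"))
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure (TRUE = allowed):\n")
  print(unclass(x))
  invisible(x)
}

# "from->to" labels of the allowed transitions, in row-major order
transition_labels <- function(structure) {
  idx <- which(t(unclass(structure)), arr.ind = FALSE)
  nm <- rownames(structure)
  out <- character(0)
  for (i in seq_len(nrow(structure)))
    for (j in seq_len(ncol(structure)))
      if (structure[i, j]) out <- c(out, paste0(nm[i], "->", nm[j]))
  out
}

state_index <- function(x) {
  states <- ad_states()
  if (is.numeric(x)) {
    ix <- as.integer(x)
    if (any(is.na(ix)) || any(ix < 1L) || any(ix > 3L)) stop("invalid state id")
    return(ix)
  }
  ix <- states[match(as.character(x), names(states))]
  if (any(is.na(ix))) stop("invalid state label: ",
                           paste(unique(setdiff(as.character(x), names(states))), collapse = ", "))
  unname(ix)
}
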