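#' CPRA category definitions
#'
#' The calculated panel reactive antibody (CPRA) percent is grouped into six
#' categories reflecting allocation-priority breakpoints: 0%, 1-79%, 80-89%,
#' 90-94%, 95-98% and 99-100%. The categories partition the integers 0-100.
#'
#' @param breaks Integer vector of lower bounds of categories 2..k (strictly
#'   increasing, within 1..100). The default reproduces the six standard
#'   sensitization categories; category 1 is always the single value 0.
#' @return A data frame with columns `index`, `lower`, `upper`, `label`, one
#'   row per category.
#' @examples
#' cpra_categories()
#' @export
cpra_categories <- function(breaks = c(1L, 80L, 90L, 95L, 99L)) {
  breaks <- as.integer(breaks)
  if (length(breaks) < 1L || is.unsorted(breaks, strictly = TRUE) ||
      breaks[1L] != 1L || any(breaks > 100L)) {
    stop("`breaks` must be strictly increasing integers starting at 1, all <= 100")
  }
  lower <- c(0L, breaks)
  upper <- c(0L, breaks[-1L] - 1L, 100L)
  label <- ifelse(lower == upper, paste0(lower, "%"),
                  paste0(lower, "-", upper, "%"))
  data.frame(index = seq_along(lower), lower = lower, upper = upper,
             label = label, stringsAsFactors = FALSE)
}

#' Assign a CPRA percent to its category
#'
#' Fractional CPRA values are floored to an integer before categorization
#' (CPRA is reported as an integer percent in registry practice), so values
#' strictly between 0 and 1 map to category 1 ("0%").
#'
#' @param cpra Numeric vector of CPRA percents in \[0, 100\].
#' @param categories Category table from [cpra_categories()].
#' @param floor_values Floor fractional percents before lookup (default TRUE).
#' @return Integer vector of category indices.
#' @examples
#' categorize_cpra(c(0, 89, 90, 100))
#' @export
categorize_cpra <- function(cpra, categories = cpra_categories(),
                            floor_values = TRUE) {
  if (!is.numeric(cpra)) stop("`cpra` must be numeric")
  bad <- which(is.na(cpra) | cpra < 0 | cpra > 100)
  if (length(bad)) {
    stop("CPRA value out of [0, 100]: ", paste(cpra[bad], collapse = ", "))
  }
  x <- if (floor_values) floor(cpra) else cpra
  idx <- findInterval(x, categories$lower)
  as.integer(categories$index[idx])
}

# absorbing outcomes in canonical order
absorbing_labels <- function() {
  c("deceased_donor_transplant", "living_donor_transplant",
    "death_or_deteriorated", "removed_other")
}

#' Build the canonical 16-state space
#'
#' Twelve transient states are the product of the six CPRA categories and the
#' two activity statuses, ordered by (category, active-before-inactive):
#' state 1 is CPRA 0% active, state 2 CPRA 0% inactive, ..., state 12 CPRA
#' 99-100% inactive. States 13-16 are the absorbing outcomes in the order
#' deceased-donor transplant, living-donor transplant, death or deterioration,
#' removal for other reasons.
#'
#' @param categories Category table from [cpra_categories()].
#' @return A data frame of class `msm_state_space` with columns `index`,
#'   `kind` ("transient"/"absorbing"), `cpra_index`, `cpra_label`, `status`
#'   and `label`; the category table is attached as attribute `categories`.
#' @examples
#' build_state_space()
#' @export
build_state_space <- function(categories = cpra_categories()) {
  k <- nrow(categories)
  transient <- data.frame(
    index = seq_len(2L * k),
    kind = "transient",
    cpra_index = rep(categories$index, each = 2L),
    cpra_label = rep(categories$label, each = 2L),
    status = rep(c("active", "inactive"), times = k),
    stringsAsFactors = FALSE
  )
  transient$label <- paste0(transient$cpra_label, " ", transient$status)
  absorbing <- data.frame(
    index = 2L * k + seq_len(4L),
    kind = "absorbing",
    cpra_index = NA_integer_,
    cpra_label = NA_character_,
    status = NA_character_,
    label = absorbing_labels(),
    stringsAsFactors = FALSE
  )
  space <- rbind(transient, absorbing)
  rownames(space) <- NULL
  attr(space, "categories") <- categories
  class(space) <- c("msm_state_space", "data.frame")
  space
}

#' @export
print.msm_state_space <- function(x, ...) {
  nt <- sum(x$kind == "transient")
  na <- sum(x$kind == "absorbing")
  cat("Multi-state space:", nt, "transient +", na, "absorbing states\n")
  print.data.frame(x, ...)
  invisible(x)
}

n_transient <- function(space) sum(space$kind == "transient")

state_index <- function(space, cpra_index, status) {
  # transient lookup by (category, status)
  key <- paste(space$cpra_index, space$status)
  match(paste(cpra_index, status), key)
}

absorbing_index <- function(space, label) {
  i <- match(label, space$label)
  if (anyNA(i)) stop("unknown absorbing state label: ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

#' Enumerate the allowed transitions
#'
#' Every transient state may move to every other transient state and to every
#' absorbing outcome, except that inactive states have no direct transition to
#' deceased-donor transplant (inactive candidates are not eligible for
#' deceased-donor offers). With the canonical space this yields
#' 12 x 15 - 6 = 174 transitions, numbered 1..174 in (from, to) order.
#'
#' @param space State space from [build_state_space()].
#' @return A data frame of class `msm_transition_structure` with columns
#'   `transition_id`, `from`, `to`.
#' @examples
#' struct <- build_transition_structure(build_state_space())
#' nrow(struct)  # 174
#' @export
build_transition_structure <- function(space = build_state_space()) {
  trans <- space$index[space$kind == "transient"]
  absb <- space$index[space$kind == "absorbing"]
  ddtx <- absorbing_index(space, "deceased_donor_transplant")
  from <- rep(trans, each = length(trans) + length(absb))
  to <- rep(c(trans, absb), times = length(trans))
  keep <- from != to &
    !(space$status[from] %in% "inactive" & to == ddtx)
  out <- data.frame(from = from[keep], to = to[keep])
  out <- out[order(out$from, out$to), , drop = FALSE]
  out <- data.frame(transition_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "space") <- space
  class(out) <- c("msm_transition_structure", "data.frame")
  out
}

#' @export
print.msm_transition_structure <- function(x, ...) {
  cat("Transition structure:", nrow(x), "allowed transitions\n")
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Dense (from, to) to transition-id lookup matrix
#'
#' @param struct Transition structure.
#' @return A states x states integer matrix, NA for disallowed pairs.
#' @export
transition_lookup <- function(struct) {
  n <- max(struct$to)
  m <- matrix(NA_integer_, n, n)
  m[cbind(struct$from, struct$to)] <- struct$transition_id
  m
}

#' Export state and transition tables as delimited text
#'
#' @param space State space from [build_state_space()].
#' @param struct Transition structure from [build_transition_structure()].
#' @param states_file,transitions_file Output paths (tab-delimited).
#' @return Invisibly, the two paths.
#' @export
write_state_tables <- function(space, struct, states_file, transitions_file) {
  st <- data.frame(state_index = space$index, kind = space$kind,
                   cpra_label = space$cpra_label, status = space$status)
  utils::write.table(st, states_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- data.frame(transition_id = struct$transition_id,
                   from_index = struct$from, to_index = struct$to)
  utils::write.table(tr, transitions_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(states_file, transitions_file))
}
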