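#' Cross plan container
#'
#' A `cross_plan` is a data.frame of unordered parent pairs (no selfs, no
#' duplicates, reciprocals collapsed to lexicographic parent order) with the
#' heterotic group of each parent and a `type` flag (`between` / `within`).
#'
#' @param parent1,parent2 character vectors of parent line IDs.
#' @param groups named character vector mapping line ID to heterotic group.
#' @return a data.frame of class `cross_plan` with columns `parent1`,
#'   `parent2`, `group1`, `group2`, `type`.
#' @export
cross_plan <- function(parent1, parent2, groups) {
  parent1 <- as.character(parent1)
  parent2 <- as.character(parent2)
  if (any(parent1 == parent2)) stopf("self crosses are not allowed in a plan")
  a <- pmin(parent1, parent2)
  b <- pmax(parent1, parent2)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate (reciprocal) pairs in plan")
  missing_lines <- setdiff(unique(c(a, b)), names(groups))
  if (length(missing_lines))
    stopf("line(s) missing from group table: %s",
          paste(head(missing_lines, 5), collapse = ", "))
  g1 <- unname(groups[a])
  g2 <- unname(groups[b])
  structure(data.frame(parent1 = a, parent2 = b, group1 = g1, group2 = g2,
                       type = ifelse(g1 == g2, "within", "between"),
                       stringsAsFactors = FALSE),
            class = c("cross_plan", "data.frame"))
}

#' Number (or list) of potential single-cross hybrids
#'
#' All unordered non-self pairs of `n` parents: `n (n - 1) / 2`.
#'
#' @param x either a single integer (number of lines; returns the count) or a
#'   character vector of line IDs (returns the full pair list).
#' @return integer count, or a data.frame with columns `parent1`, `parent2`
#'   in lexicographic order.
#' @examples
#' enumerate_potential_hybrids(266)  # 35245
#' @export
enumerate_potential_hybrids <- function(x) {
  if (is.numeric(x) && length(x) == 1) {
    n <- as.integer(x)
    if (n < 2) stopf("need at least 2 lines to form a hybrid")
    return(n * (n - 1L) / 2L)
  }
  ids <- sort(as.character(x))
  if (length(ids) < 2) stopf("need at least 2 lines to form a hybrid")
  if (anyDuplicated(ids)) stopf("duplicate line IDs")
  pairs <- t(combn(ids, 2))
  data.frame(parent1 = pairs[, 1], parent2 = pairs[, 2],
             stringsAsFactors = FALSE)
}

#' Generate a sparse partial diallel crossing plan between heterotic groups
#'
#' Builds a randomized plan in which every line participates at least once
#' and the realized fraction of between-group crosses tracks
#' `between_fraction`. A first pass pairs each line once (guaranteeing
#' coverage), preferring between-group partners with probability
#' `between_fraction`; remaining crosses are then filled by sampling pairs of
#' the chosen type uniformly among unused pairs, lightly favouring
#' under-used parents.
#'
#' @param groups named character vector: line ID -> heterotic group.
#' @param n_crosses total number of crosses; defaults to
#'   `round(crosses_per_line * n / 2)`.
#' @param crosses_per_line target average participation per line (used only
#'   when `n_crosses` is missing; default 7).
#' @param between_fraction desired fraction of between-group crosses
#'   (default 0.8).
#' @param seed RNG seed; the plan is a deterministic function of
#'   (groups, sizes, seed).
#' @return a [cross_plan()].
#' @export
generate_spdc_plan <- function(groups, n_crosses = NULL, crosses_per_line = 7,
                               between_fraction = 0.8, seed = 1) {
  lines <- names(groups)
  n <- length(lines)
  if (n < 2) stopf("need at least 2 lines")
  if (is.null(n_crosses)) n_crosses <- round(crosses_per_line * n / 2)
  n_crosses <- as.integer(n_crosses)
  max_pairs <- n * (n - 1) / 2
  if (n_crosses < ceiling(n / 2))
    stopf("infeasible: %d crosses cannot cover %d lines (need >= %d)",
          n_crosses, n, ceiling(n / 2))
  if (n_crosses > max_pairs)
    stopf("infeasible: %d crosses exceed the %d possible pairs", n_crosses,
          max_pairs)
  if (length(unique(groups)) < 2 && between_fraction > 0)
    between_fraction <- 0
  set.seed(as.integer(seed))

  used <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(i, j) paste(min(i, j), max(i, j))
  part <- setNames(integer(n), lines)
  p1 <- character(0); p2 <- character(0)
  add_pair <- function(i, j) {
    assign(key(i, j), TRUE, envir = used)
    p1 <<- c(p1, min(i, j)); p2 <<- c(p2, max(i, j))
    part[c(i, j)] <<- part[c(i, j)] + 1L
  }

  # coverage pass: walk lines in random order, pair each uncovered line
  for (ln in sample(lines)) {
    if (part[ln] > 0 || length(p1) >= n_crosses) next
    want_between <- runif(1) < between_fraction
    cand <- lines[lines != ln]
    same <- groups[cand] == groups[ln]
    pool <- if (want_between && any(!same)) cand[!same]
            else if (!want_between && any(same)) cand[same] else cand
    # prefer partners that are themselves uncovered
    unc <- pool[part[pool] == 0]
    if (length(unc)) pool <- unc
    free <- pool[!vapply(pool, function(q)
      exists(key(ln, q), envir = used), logical(1))]
    if (!length(free)) free <- pool
    j <- if (length(free) == 1) free else sample(free, 1)
    if (!exists(key(ln, j), envir = used)) add_pair(ln, j)
  }
  if (any(part == 0) && length(p1) >= n_crosses)
    stopf("infeasible: coverage requires more than %d crosses", n_crosses)

  # fill pass
  guard <- 0L
  while (length(p1) < n_crosses) {
    guard <- guard + 1L
    if (guard > 200L * n_crosses)
      stopf("could not place %d crosses with the requested type mix",
            n_crosses)
    want_between <- runif(1) < between_fraction
    w <- 1 / (1 + part)
    i <- sample(lines, 1, prob = w)
    cand <- lines[lines != i]
    same <- groups[cand] == groups[i]
    pool <- if (want_between && any(!same)) cand[!same]
            else if (!want_between && any(same)) cand[same] else cand
    j <- sample(pool, 1, prob = 1 / (1 + part[pool]))
    if (!exists(key(i, j), envir = used)) add_pair(i, j)
  }
  cross_plan(p1, p2, groups)
}

#' Summarise a crossing plan
#'
#' @param plan a [cross_plan()].
#' @return list with `n_crosses`, `n_between`, `n_within`, `participation`
#'   (named counts per line, zero-filled over the plan's lines),
#'   `participation_range`, mean participation, and the group x group
#'   cross-count matrix.
#' @export
plan_stats <- function(plan) {
  stopifnot(inherits(plan, "cross_plan"))
  lines <- sort(unique(c(plan$parent1, plan$parent2)))
  part <- table(factor(c(plan$parent1, plan$parent2), levels = lines))
  gl <- sort(unique(c(plan$group1, plan$group2)))
  gmat <- matrix(0L, length(gl), length(gl), dimnames = list(gl, gl))
  for (k in seq_len(nrow(plan))) {
    a <- plan$group1[k]; b <- plan$group2[k]
    gmat[a, b] <- gmat[a, b] + 1L
    if (a != b) gmat[b, a] <- gmat[b, a] + 1L
  }
  list(n_crosses = nrow(plan),
       n_between = sum(plan$type == "between"),
       n_within = sum(plan$type == "within"),
       participation = c(part),
       participation_range = range(as.integer(part)),
       mean_participation = 2 * nrow(plan) / length(lines),
       group_matrix = gmat)
}

#' Write / read a cross plan as TSV
#' @param plan a [cross_plan()].
#' @param path file path.
#' @return the path (write) or a `cross_plan` (read).
#' @export
write_cross_plan <- function(plan, path) {
  data.table::fwrite(as.data.frame(plan), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_cross_plan
#' @export
read_cross_plan <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  groups <- c(setNames(df$group1, df$parent1), setNames(df$group2, df$parent2))
  cross_plan(df$parent1, df$parent2, groups[!duplicated(names(groups))])
}
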