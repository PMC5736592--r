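# Dominance rank, pedigree relatedness, close-kin counts, group tenure.

#' Infer an ordinal dominance hierarchy from win-loss records
#'
#' Hierarchies are computed separately per group, year and sex.  Each
#' dyad's win proportion P_ij = wins_ij / (wins_ij + wins_ji) enters
#' David's score DS_i = w_i + w2_i - l_i - l2_i, where w_i is the sum of
#' i's win proportions, w2_i the sum of those proportions weighted by
#' the opponents' w, and l, l2 the loss-side analogues; dyads that never
#' interacted contribute nothing.  Individuals are ranked by decreasing
#' score; ties are broken by total wins, then by id order.
#'
#' @param agonistic Data frame of agonistic records (`winner`, `loser`,
#'   `group`, `year`, `count`).
#' @param group,year Group-year to rank.
#' @param sex Sex class (`"F"` or `"M"`).
#' @param ids Character vector of the same-sex adults to rank (ids with
#'   no recorded bouts still receive a rank, at the bottom by score 0).
#' @return Data frame `id`, `davids_score`, `ordinal_rank` (1 = top).
#' @export
infer_hierarchy <- function(agonistic, group, year, sex, ids) {
  if (length(ids) < 2)
    .abort("need >= 2 same-sex individuals to rank", "isonet_schema_error")
  ago <- agonistic[agonistic$group == group & agonistic$year == year &
                     agonistic$winner %in% ids & agonistic$loser %in% ids, ,
                   drop = FALSE]
  if (!nrow(ago))
    .abort(sprintf("no agonistic data for group %s year %s sex %s",
                   group, year, sex), "isonet_no_rank_error")
  n <- length(ids)
  wins <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(ago)))
    wins[ago$winner[r], ago$loser[r]] <-
      wins[ago$winner[r], ago$loser[r]] + ago$count[r]
  tot <- wins + t(wins)
  P <- ifelse(tot > 0, wins / tot, 0)
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.vector(P %*% w)
  l2 <- as.vector(t(P) %*% l)
  ds <- w + w2 - l - l2
  ord <- order(-ds, -rowSums(wins), ids)
  data.frame(id = ids[ord], davids_score = ds[ord],
             ordinal_rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Percentage of same-sex groupmates outranked, and rank class
#'
#' Converts ordinal ranks to the percentage of same-sex groupmates an
#' animal outranks, 100 * (n - rank) / (n - 1), and classes animals as
#' high ranking when they outrank more than 80 percent of their
#' group/sex, low otherwise.  With a single same-sex animal the
#' percentage is undefined and the animal is flagged (`NA`) so it can be
#' dropped from rank-using models.
#'
#' @param hierarchy Data frame from [infer_hierarchy()].
#' @param high_threshold Percentage above which an animal is classed
#'   high ranking (default 80).
#' @return The hierarchy data frame with `percent_outranked` and
#'   `rank_class` (`"high"`/`"low"`) columns added.
#' @export
percent_outranked <- function(hierarchy, high_threshold = 80) {
  n <- nrow(hierarchy)
  pct <- if (n > 1) 100 * (n - hierarchy$ordinal_rank) / (n - 1)
         else NA_real_
  hierarchy$percent_outranked <- pct
  hierarchy$rank_class <- ifelse(is.na(pct), NA_character_,
                                 ifelse(pct > high_threshold, "high", "low"))
  hierarchy
}

#' Additive relationship (coefficient of relatedness) from a pedigree
#'
#' Computes the full additive relationship matrix A = 2 * kinship by the
#' standard recursion on a pedigree sorted parents-first: founders are
#' taken as unrelated and non-inbred; A_ii = 1 + F_i.  Mother-offspring
#' and full-sibling pairs have r = 0.5, half siblings 0.25.
#'
#' @param pedigree Data frame `id`, `mother_id`, `father_id`.
#' @return Symmetric matrix of relatedness coefficients with id dimnames.
#' @export
relatedness_matrix <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  # topological order: parents before offspring
  depth <- stats::setNames(rep(NA_real_, n), ids)
  get_depth <- function(id) {
    if (!is.na(depth[id])) return(depth[id])
    row <- match(id, ids)
    ps <- c(pedigree$mother_id[row], pedigree$father_id[row])
    ps <- ps[!is.na(ps)]
    d <- if (!length(ps)) 0 else 1 + max(vapply(ps, get_depth, numeric(1)))
    depth[id] <<- d
    d
  }
  for (id in ids) get_depth(id)
  ord <- order(depth[ids])
  ids_o <- ids[ord]
  mo <- match(pedigree$mother_id[ord], ids_o)
  fa <- match(pedigree$father_id[ord], ids_o)
  A <- matrix(0, n, n, dimnames = list(ids_o, ids_o))
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    rm_ <- if (!is.na(mo[i])) A[mo[i], prev] else numeric(length(prev))
    rf_ <- if (!is.na(fa[i])) A[fa[i], prev] else numeric(length(prev))
    if (length(prev)) {
      A[i, prev] <- 0.5 * (rm_ + rf_)
      A[prev, i] <- A[i, prev]
    }
    Fi <- if (!is.na(mo[i]) && !is.na(fa[i])) 0.5 * A[mo[i], fa[i]] else 0
    A[i, i] <- 1 + Fi
  }
  A[ids, ids, drop = FALSE]
}

#' @rdname relatedness_matrix
#' @param i,j Ids present in the pedigree.
#' @return `relatedness()` returns the scalar coefficient for one pair.
#' @export
relatedness <- function(pedigree, i, j) {
  if (!all(c(i, j) %in% pedigree$id))
    .abort(paste("id(s) absent from pedigree:",
                 paste(setdiff(c(i, j), pedigree$id), collapse = ", ")),
           "isonet_integrity_error")
  A <- relatedness_matrix(pedigree)
  unname(A[i, j])
}

#' Number of close adult female kin present in a group-year
#'
#' Counts, for a female subject, the other females with coefficient of
#' relatedness exactly 0.5 (mother, daughters, full sisters), aged at
#' least `min_age`, that were members of the same group that year.
#'
#' @param tables A [demography_tables()] object (pedigree required).
#' @param id Focal female id.
#' @param group,year Group-year of interest.
#' @param min_age Adult threshold in years (default 6).
#' @param A Optional precomputed [relatedness_matrix()] (for speed when
#'   counting kin for many subjects).
#' @return Integer count.
#' @export
count_close_adult_female_kin <- function(tables, id, group, year,
                                         min_age = 6, A = NULL) {
  ped <- tables$pedigree
  if (is.null(ped))
    .abort("no pedigree table available", "isonet_schema_error")
  if (is.null(A)) A <- relatedness_matrix(ped)
  mem <- tables$membership
  present <- mem$id[mem$group == group & mem$year == year]
  ind <- tables$individuals
  cand <- present[present != id]
  cand <- cand[ind$sex[match(cand, ind$id)] == "F"]
  age <- year - ind$birth_year[match(cand, ind$id)]
  cand <- cand[age >= min_age]
  cand <- cand[cand %in% rownames(A)]
  if (!(id %in% rownames(A)) || !length(cand)) return(0L)
  sum(abs(A[id, cand] - 0.5) < 1e-9)
}

#' Male group tenure in whole years
#'
#' Number of consecutive years immediately before `year` in which the
#' male was a member of the same group; 0 for males that entered the
#' group in the year before data collection (a gap in membership resets
#' tenure).
#'
#' @param membership Membership data frame (`id`, `group`, `year`).
#' @param id Male id.
#' @param group,year Group-year of interest.
#' @return Integer tenure in years.
#' @export
tenure <- function(membership, id, group, year) {
  yrs <- membership$year[membership$id == id & membership$group == group]
  t <- 0L
  while ((year - t - 1L) %in% yrs) t <- t + 1L
  t
}
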