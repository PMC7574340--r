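## Area-level disadvantage covariate: aggregation from sub-regions and scaling.

#' Population-weighted aggregation of sub-region scores
#'
#' Area-level socio-economic indices (SEIFA-like) are published at a
#' sub-regional level; the region-level covariate is the population-weighted
#' average of the sub-region scores within each region. Regions whose total
#' sub-region population falls below `min_population` cannot support a
#' meaningful index and yield a missing score (flagged), emulating the
#' near-empty areas for which no index can be calculated.
#'
#' @param table data frame with columns `sub_id`, `region_id`, `score`,
#'   `population`.
#' @param region_ids vector of region identifiers defining output order;
#'   defaults to order of first appearance in `table`.
#' @param min_population total-population threshold below which the region
#'   score is set missing (default 10).
#' @param allow_missing if `FALSE` (default), a region with zero total
#'   population is an error rather than a missing score.
#' @return data frame with `region_id`, `score` (NA where missing),
#'   `population`, `score_missing`.
#' @examples
#' tab <- data.frame(sub_id = 1:2, region_id = "A",
#'                   score = c(1000, 900), population = c(100, 300))
#' aggregate_weighted(tab)$score  # 925
#' @export
aggregate_weighted <- function(table, region_ids = NULL,
                               min_population = 10, allow_missing = FALSE) {
  req <- c("sub_id", "region_id", "score", "population")
  if (!all(req %in% names(table)))
    stop("table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(table$sub_id)) stop("duplicate sub_id")
  if (any(table$population < 0)) stop("negative population")
  if (is.null(region_ids)) {
    region_ids <- unique(as.character(table$region_id))
  } else {
    region_ids <- as.character(region_ids)
    unknown <- setdiff(unique(as.character(table$region_id)), region_ids)
    if (length(unknown))
      stop("unknown parent region id: ", paste(unknown, collapse = ", "))
  }
  idx <- match(as.character(table$region_id), region_ids)
  pop <- vapply(seq_along(region_ids), function(r)
    sum(table$population[idx == r]), numeric(1))
  wsum <- vapply(seq_along(region_ids), function(r)
    sum(table$score[idx == r] * table$population[idx == r]), numeric(1))
  score <- ifelse(pop > 0, wsum / pop, NA_real_)
  missing <- pop < min_population
  if (any(pop == 0) && !allow_missing)
    stop("zero total population for region ",
         paste(region_ids[pop == 0], collapse = ", "),
         " (set allow_missing = TRUE to flag instead)")
  score[missing] <- NA_real_
  data.frame(region_id = region_ids, score = score, population = pop,
             score_missing = missing, stringsAsFactors = FALSE)
}

#' Standardize a covariate to zero mean and unit standard deviation
#'
#' Centring/scaling is computed over non-missing entries (sample sd,
#' n - 1 denominator); missing entries propagate. The transform parameters
#' are returned so out-of-sample values can be placed on the same scale.
#'
#' @param x numeric vector, possibly with `NA`s.
#' @return list with `z` (standardized vector), `center`, `scale`.
#' @export
standardize <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) stop("need at least 2 non-missing values")
  ctr <- mean(obs)
  scl <- sd(obs)
  if (scl == 0) stop("zero spread: covariate cannot be standardized")
  list(z = (x - ctr) / scl, center = ctr, scale = scl)
}
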