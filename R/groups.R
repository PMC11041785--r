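#' Seasonal group statistics of albedo and NEP (growing season vs dormancy vs snow)
#'
#' Summarises per-window condition labels into per-group statistics: for
#' each group and condition, NEP (gC m-2 month-1) is arithmetically
#' averaged across sites while albedo is the ratio of summed pairwise
#' available SW_OUT and SW_IN pooled over the group's sites.  Conditions
#' contributing less than \code{min_fraction} of a site's total period are
#' neglected for that site (applied to dormant and snow; the growing season
#' is always retained).  Delta columns (dormant / snow minus active) are
#' computed against the active values of only the remaining sites, i.e.
#' those that exhibit the condition.  Standard errors (sd across sites /
#' sqrt(n)) are reported for groups with more than one site.
#'
#' Groups comprise every IGBP class, species-dominated subsets (sites with
#' a recorded dominant species, >= 75 percent coverage) contrasted with the
#' remaining "Mix" sites of the same class, and the forest contrast groups
#' broadleaf (DBF, EBF), needleleaf (ENF), deciduous (DBF) and evergreen
#' (EBF, ENF) forests.
#'
#' @param windows per-site labelled windows bound into one data.frame
#'   (columns site_id, condition, n_records, sw_in_sum, sw_out_sum,
#'   nep_month), e.g. rbind of \code{\link{process_site}} outputs with a
#'   site_id column added.
#' @param meta site metadata (igbp, species).
#' @param min_fraction neglect threshold for a condition's share of a
#'   site's total period (default 0.10).
#' @return data.frame with one row per group: n_sites, alpha_act (+ se),
#'   nep_act (+ se), d_alpha_dorm, d_nep_dorm, n_dorm, d_alpha_snow,
#'   d_nep_snow, n_snow.  Attribute \code{window_counts} records kept and
#'   dropped window totals.
#' @export
group_seasonal_stats <- function(windows, meta, min_fraction = 0.10) {
  w <- windows[!is.na(windows$condition), , drop = FALSE]
  # per-site condition shares of the total period
  total_rec <- tapply(w$n_records, w$site_id, sum)
  w$share <- w$n_records / as.numeric(total_rec[w$site_id])
  cond_share <- stats::aggregate(share ~ site_id + condition, w, sum)
  drop_key <- with(cond_share,
                   paste(site_id, condition)[share < min_fraction &
                                               condition != "active"])
  dropped <- paste(w$site_id, w$condition) %in% drop_key
  n_dropped <- sum(w$n_records[dropped])
  w <- w[!dropped, , drop = FALSE]

  # per site x condition aggregates
  w$nep_weighted <- w$nep_month * w$n_records
  agg <- stats::aggregate(
    cbind(sw_in_sum, sw_out_sum, nep_weighted, n_records) ~
      site_id + condition, w, sum)
  agg$nep_month <- agg$nep_weighted / agg$n_records
  agg$alpha <- agg$sw_out_sum / agg$sw_in_sum

  group_defs <- list()
  for (cls in unique(meta$igbp))
    group_defs[[cls]] <- meta$site_id[meta$igbp == cls]
  has_sp <- !is.na(meta$species) & meta$species != ""
  for (cls in unique(meta$igbp[has_sp])) {
    in_cls <- meta$igbp == cls
    for (sp in unique(meta$species[in_cls & has_sp]))
      group_defs[[paste(cls, sp, sep = ": ")]] <-
        meta$site_id[in_cls & has_sp & meta$species == sp]
    if (any(in_cls & !has_sp))
      group_defs[[paste(cls, "Mix", sep = ": ")]] <-
        meta$site_id[in_cls & !has_sp]
  }
  group_defs[["All broad-leaved forests"]] <-
    meta$site_id[meta$igbp %in% c("DBF", "EBF")]
  group_defs[["All needle-leaved forests"]] <-
    meta$site_id[meta$igbp %in% "ENF"]
  group_defs[["All deciduous-leaved forests"]] <-
    meta$site_id[meta$igbp %in% "DBF"]
  group_defs[["All evergreen-leaved forests"]] <-
    meta$site_id[meta$igbp %in% c("EBF", "ENF")]
  group_defs <- group_defs[vapply(group_defs, length, integer(1)) > 0]

  cond_stats <- function(sites, condition) {
    a <- agg[agg$site_id %in% sites & agg$condition == condition, ,
             drop = FALSE]
    if (!nrow(a)) return(NULL)
    list(sites = a$site_id,
         alpha = sum(a$sw_out_sum) / sum(a$sw_in_sum),
         alpha_se = if (nrow(a) > 1) sd(a$alpha) / sqrt(nrow(a)) else NA_real_,
         nep = mean(a$nep_month),
         nep_se = if (nrow(a) > 1) sd(a$nep_month) / sqrt(nrow(a))
         else NA_real_,
         n = nrow(a))
  }

  rows <- lapply(names(group_defs), function(gname) {
    sites <- group_defs[[gname]]
    act <- cond_stats(sites, "active")
    if (is.null(act)) return(NULL)
    out <- data.frame(group = gname, n_sites = act$n,
                      alpha_act = act$alpha, alpha_act_se = act$alpha_se,
                      nep_act = act$nep, nep_act_se = act$nep_se,
                      d_alpha_dorm = NA_real_, d_nep_dorm = NA_real_,
                      n_dorm = 0L,
                      d_alpha_snow = NA_real_, d_nep_snow = NA_real_,
                      n_snow = 0L, stringsAsFactors = FALSE)
    for (cond in c("dormant", "snow")) {
      cs <- cond_stats(sites, cond)
      if (is.null(cs)) next
      base <- cond_stats(cs$sites, "active")  # remaining sites only
      suffix <- if (cond == "dormant") "dorm" else "snow"
      out[[paste0("d_alpha_", suffix)]] <- cs$alpha -
        (if (is.null(base)) NA_real_ else base$alpha)
      out[[paste0("d_nep_", suffix)]] <- cs$nep -
        (if (is.null(base)) NA_real_ else base$nep)
      out[[paste0("n_", suffix)]] <- cs$n
    }
    out
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(res, "window_counts") <- c(kept = sum(w$n_records),
                                  dropped = n_dropped)
  res
}
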