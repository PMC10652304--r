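#' Percent change in PTM quantity at one site
#'
#' The elementary unit of the %d-PTM/site metric: replicate quantities are
#' averaged within each condition, then the treated condition mean is
#' expressed as a signed percent change relative to the vehicle mean,
#' `100 * (mean(treated) - mean(vehicle)) / mean(vehicle)`.
#'
#' A site with zero vehicle signal but nonzero treated signal has no defined
#' percent change; it is returned as `NA` carrying a `"new_site"` status
#' attribute and is excluded from per-protein averages by default. With
#' `new_site = "pseudocount"` a small count is added to both condition means
#' so such sites yield a (large, finite) value. A site silent in both
#' conditions returns `NA` with status `"null"`.
#'
#' @param vehicle_quantities,treated_quantities Non-negative per-replicate
#'   quantities for the vehicle and treated conditions.
#' @param new_site `"exclude"` (default) or `"pseudocount"`.
#' @param pseudocount Count added to both means under the pseudocount policy.
#' @return A numeric scalar (signed percent), possibly `NA` with a `status`
#'   attribute `"new_site"` or `"null"`.
#' @examples
#' site_percent_change(c(10, 10), c(5, 5))  # -50
#' @export
site_percent_change <- function(vehicle_quantities, treated_quantities,
                                new_site = c("exclude", "pseudocount"),
                                pseudocount = 0.5) {
  new_site <- match.arg(new_site)
  stopifnot(length(vehicle_quantities) >= 1L, length(treated_quantities) >= 1L,
            all(vehicle_quantities >= 0), all(treated_quantities >= 0))
  mv <- mean(vehicle_quantities)
  mt <- mean(treated_quantities)
  if (mv == 0) {
    if (mt == 0) return(structure(NA_real_, status = "null"))
    if (new_site == "exclude") return(structure(NA_real_, status = "new_site"))
    mv <- mv + pseudocount
    mt <- mt + pseudocount
  }
  100 * (mt - mv) / mv
}

# Validate an evidence data.frame against the PTM evidence contract.
check_evidence <- function(evidence) {
  needed <- c("protein_id", "site", "modification", "condition", "replicate", "quantity")
  missing <- setdiff(needed, names(evidence))
  if (length(missing)) {
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(evidence$quantity < 0, na.rm = TRUE)) stop("negative quantities in evidence")
  key <- do.call(paste, evidence[needed[-6]])
  if (anyDuplicated(key)) {
    stop("duplicate (protein, site, modification, condition, replicate) rows")
  }
  invisible(evidence)
}

# Site-level %-change table for one vehicle/treated condition pair: one row
# per (protein_id, site, modification) with the percent change and status.
site_change_table <- function(evidence, condition_pair,
                              new_site = "exclude", pseudocount = 0.5) {
  check_evidence(evidence)
  stopifnot(all(c("vehicle", "treated") %in% names(condition_pair)))
  ev <- evidence[evidence$condition %in% unlist(condition_pair), , drop = FALSE]
  if (!nrow(ev)) stop("no evidence rows match the condition pair")
  key <- interaction(ev$protein_id, ev$site, ev$modification, drop = TRUE, sep = "\r")
  pieces <- split(ev, key)
  rows <- lapply(pieces, function(d) {
    pc <- site_percent_change(
      d$quantity[d$condition == condition_pair[["vehicle"]]],
      d$quantity[d$condition == condition_pair[["treated"]]],
      new_site = new_site, pseudocount = pseudocount
    )
    data.frame(protein_id = d$protein_id[1], site = d$site[1],
               modification = d$modification[1],
               pct_change = as.numeric(pc),
               status = attr(pc, "status") %||% "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PTM change per site, aggregated per protein or per modification
#'
#' Computes the site-level percent changes for a vehicle/treated condition
#' pair and aggregates them over each protein's modified (site, modification)
#' pairs — or, with `by = "modification"`, over each chemical modification
#' across proteins. The default aggregate is the unweighted mean across
#' sites, which normalizes proteins of different site counts onto a common
#' per-site scale; `aggregate = "sum"` totals the site changes instead.
#'
#' Entries with no valid site (all sites new or null) are marked
#' `insufficient_data = TRUE` with an `NA` change, matching the convention
#' that "no change" and "insufficient data" are distinct states.
#'
#' @param evidence A PTM evidence data.frame with columns `protein_id`,
#'   `site`, `modification`, `condition`, `replicate`, `quantity`.
#' @param condition_pair Named character vector/list with elements `vehicle`
#'   and `treated` naming condition labels in `evidence`.
#' @param by `"protein"` or `"modification"`.
#' @param aggregate `"mean"` (default) or `"sum"` across sites.
#' @param zero_tolerance Absolute percent below which a change counts as zero
#'   for the net sign.
#' @param new_site,pseudocount New-site policy, see [site_percent_change()].
#' @return A data.frame of class `ox_ptm_change` with columns `id`,
#'   `pct_change_per_site`, `n_sites`, `net_sign`, `insufficient_data`.
#' @export
ptm_change_table <- function(evidence, condition_pair,
                             by = c("protein", "modification"),
                             aggregate = c("mean", "sum"),
                             zero_tolerance = 1e-9,
                             new_site = "exclude", pseudocount = 0.5) {
  by <- match.arg(by)
  aggregate <- match.arg(aggregate)
  sites <- site_change_table(evidence, condition_pair, new_site, pseudocount)
  group <- if (by == "protein") sites$protein_id else sites$modification
  pieces <- split(sites, group)
  rows <- lapply(names(pieces), function(g) {
    ok <- pieces[[g]]$status == "ok"
    vals <- pieces[[g]]$pct_change[ok]
    if (!length(vals)) {
      return(data.frame(id = g, pct_change_per_site = NA_real_, n_sites = 0L,
                        net_sign = NA_integer_, insufficient_data = TRUE,
                        stringsAsFactors = FALSE))
    }
    change <- if (aggregate == "mean") mean(vals) else sum(vals)
    data.frame(id = g, pct_change_per_site = change, n_sites = length(vals),
               net_sign = sign_of(change, zero_tolerance),
               insufficient_data = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ox_ptm_change", "data.frame")
  out
}

sign_of <- function(x, zero_tolerance) {
  as.integer(ifelse(abs(x) <= zero_tolerance, 0L, sign(x)))
}

#' @rdname ptm_change_table
#' @param protein_id,modification A single id to extract (the corresponding
#'   one-row entry; an insufficient-data entry if absent from the evidence).
#' @param ... Further arguments passed to `ptm_change_table()`.
#' @export
protein_ptm_change <- function(evidence, protein_id, condition_pair, ...) {
  tab <- ptm_change_table(evidence, condition_pair, by = "protein", ...)
  entry_or_insufficient(tab, protein_id)
}

#' @rdname ptm_change_table
#' @export
modification_ptm_change <- function(evidence, modification, condition_pair, ...) {
  tab <- ptm_change_table(evidence, condition_pair, by = "modification", ...)
  entry_or_insufficient(tab, modification)
}

entry_or_insufficient <- function(tab, id) {
  hit <- tab[tab$id == id, , drop = FALSE]
  if (!nrow(hit)) {
    hit <- data.frame(id = id, pct_change_per_site = NA_real_, n_sites = 0L,
                      net_sign = NA_integer_, insufficient_data = TRUE,
                      stringsAsFactors = FALSE)
  }
  rownames(hit) <- NULL
  hit
}

#' Grand sum of PTM changes
#'
#' Total of `pct_change_per_site` over the (valid) entries of a change table:
#' the single signed number summarizing whether a treatment added or removed
#' oxidative modification overall. Computed identically whether the table was
#' aggregated per protein or per modification.
#'
#' @param table An `ox_ptm_change` table (or any data.frame with a
#'   `pct_change_per_site` column).
#' @return A signed percent (numeric scalar).
#' @export
grand_sum <- function(table) {
  vals <- table$pct_change_per_site
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no valid entries to sum")
  sum(vals)
}

#' Census of change directions
#'
#' Partitions entries into decreasing / increasing / unchanged using
#' `|x| <= zero_tolerance` as the "unchanged" band. Accepts a change table or
#' a bare vector of signed values (percent changes or -1/0/+1 net signs).
#'
#' @param table An `ox_ptm_change` table or a numeric vector.
#' @param zero_tolerance Absolute value at or below which an entry counts as
#'   unchanged.
#' @return Named integer vector `c(decreasing, increasing, unchanged)`; `NA`
#'   entries are dropped.
#' @export
sign_census <- function(table, zero_tolerance = 1e-9) {
  vals <- if (is.numeric(table)) table else table$pct_change_per_site
  vals <- vals[!is.na(vals)]
  s <- sign_of(vals, zero_tolerance)
  c(decreasing = sum(s == -1L), increasing = sum(s == 1L), unchanged = sum(s == 0L))
}

#' Overlay PTM changes on LFQ abundance changes
#'
#' Outer join of a per-protein PTM change table with a per-protein LFQ
#' (label-free quantification) table, so modification shifts can be read
#' against abundance shifts protein by protein. Proteins present in only one
#' table keep `NA` in the other's columns; PTM-side `NA` rows carry
#' `insufficient_data = TRUE`.
#'
#' @param ptm_table An `ox_ptm_change` table aggregated by protein.
#' @param lfq_table A data.frame with `protein_id` and at least one value
#'   column (e.g. `log2_ratio`).
#' @return The joined data.frame, one row per protein in either table.
#' @export
overlay_lfq <- function(ptm_table, lfq_table) {
  stopifnot("protein_id" %in% names(lfq_table))
  ptm <- as.data.frame(ptm_table)
  names(ptm)[names(ptm) == "id"] <- "protein_id"
  out <- merge(ptm, lfq_table, by = "protein_id", all = TRUE)
  out$insufficient_data[is.na(out$insufficient_data)] <- TRUE
  out[order(out$protein_id), , drop = FALSE]
}

#' Pearson correlation with a bootstrap confidence band
#'
#' Pearson's r and the least-squares line for paired per-protein values, with
#' a 95% percentile bootstrap confidence interval for the regression slope
#' from case resampling. Pairs with `NA` in either variable are dropped
#' before fitting.
#'
#' @param x,y Numeric vectors of equal length (paired per-protein values).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level of the percentile band.
#' @return A list of class `ox_correlation` with `pearson_r`, `slope`,
#'   `intercept`, `ci_low`, `ci_high` (slope band), `n_points`, `n_boot`,
#'   `seed`.
#' @export
correlate <- function(x, y, n_boot = 1000L, seed = 0L, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant x or y: Pearson correlation undefined")
  }
  slope_of <- function(x, y) stats::cov(x, y) / stats::var(x)
  slope <- slope_of(x, y)
  res <- list(
    pearson_r = stats::cor(x, y),
    slope = slope,
    intercept = mean(y) - slope * mean(x),
    n_points = n, n_boot = as.integer(n_boot), seed = as.integer(seed)
  )
  set.seed(seed)
  boot_slopes <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::var(x[i]) == 0) return(NA_real_)
    slope_of(x[i], y[i])
  }, numeric(1))
  ci <- stats::quantile(boot_slopes, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  res$ci_low <- ci[1]
  res$ci_high <- ci[2]
  structure(res, class = "ox_correlation")
}
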