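#' Integrated density of a channel over a region
#'
#' Sum of pixel intensities of a single-channel image over a mask — the
#' quantity read off each fluorescence channel of a coculture or
#' monoculture macrocolony image.
#'
#' @param image Single-channel [colony_image()].
#' @param mask Logical matrix; `NULL` sums the full frame.
#' @return Summed intensity (scalar).
#' @export
integrated_density <- function(image, mask = NULL) {
  stopifnot(inherits(image, "colony_image"))
  if (is_rgb(image)) stop("integrated density requires a single channel")
  if (is.null(mask)) return(sum(image$pixels))
  stopifnot(is.logical(mask), all(dim(mask) == dim(image$pixels)))
  if (!any(mask)) stop("empty mask")
  sum(image$pixels[mask])
}

#' Competition quartet from four measured densities
#'
#' @param co_A,co_B Integrated densities of channels A (green/GFP) and B
#'   (red/mKate) in the coculture image, `>= 0`.
#' @param mono_A,mono_B Integrated densities of the corresponding
#'   monocultures, `> 0`.
#' @return An object of class `"competition_quartet"`.
#' @export
competition_quartet <- function(co_A, co_B, mono_A, mono_B) {
  stopifnot(co_A >= 0, co_B >= 0, mono_A > 0, mono_B > 0)
  structure(list(co_A = co_A, co_B = co_B,
                 mono_A = mono_A, mono_B = mono_B),
            class = "competition_quartet")
}

#' Relative strain abundance with monoculture normalization
#'
#' Coculture channel densities are divided by the matching monoculture
#' densities to cancel differences in reporter expression strength
#' (GFP vs mKate brightness), then expressed as percentages of the total
#' normalized signal:
#' `a' = co_A / mono_A`, `b' = co_B / mono_B`,
#' `pct_A = 100 a' / (a' + b')`, `pct_B = 100 - pct_A`.
#' The result is invariant to rescaling either channel's gain — the purpose
#' of the normalization.
#'
#' @param quartet A `"competition_quartet"` (from [competition_quartet()] or
#'   [sim_competition_quartet()]), or a list/one-row data frame with fields
#'   `co_A`, `co_B`, `mono_A`, `mono_B`.
#' @return An object of class `"abundance_result"`: list with `pct_A`,
#'   `pct_B` (summing to 100 exactly).
#' @examples
#' relative_abundance(competition_quartet(30, 10, 60, 40))  # 66.67 / 33.33
#' @export
relative_abundance <- function(quartet) {
  q <- quartet
  stopifnot(all(c("co_A", "co_B", "mono_A", "mono_B") %in% names(q)))
  stopifnot(q$co_A >= 0, q$co_B >= 0, q$mono_A > 0, q$mono_B > 0)
  a <- q$co_A / q$mono_A
  b <- q$co_B / q$mono_B
  if (a + b == 0) stop("no signal: both normalized densities are zero")
  pct_A <- 100 * a / (a + b)
  structure(list(pct_A = pct_A, pct_B = 100 - pct_A),
            class = "abundance_result")
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(sprintf("Relative abundance: A %.2f%% / B %.2f%%\n", x$pct_A, x$pct_B))
  invisible(x)
}

#' Abundance table for many competition pairs
#'
#' Vectorized [relative_abundance()] over a data frame of quartets.
#'
#' @param quartets Data frame with columns `pair_id`, `co_A`, `co_B`,
#'   `mono_A`, `mono_B`.
#' @return Data frame with `pair_id`, `pct_A`, `pct_B`.
#' @export
abundance_table <- function(quartets) {
  stopifnot(is.data.frame(quartets),
            all(c("pair_id", "co_A", "co_B", "mono_A", "mono_B") %in%
                  names(quartets)))
  res <- lapply(seq_len(nrow(quartets)), function(i)
    relative_abundance(as.list(quartets[i, ])))
  data.frame(pair_id = quartets$pair_id,
             pct_A = vapply(res, `[[`, numeric(1), "pct_A"),
             pct_B = vapply(res, `[[`, numeric(1), "pct_B"))
}

#' Tally outgrowth-screening records
#'
#' Exact per-strain tallies of peripheral-outgrowth screening: colonies
#' screened, outgrowths observed, the outgrowth frequency, and the
#' morphotype-class breakdown. Experiments are reported independently by
#' default (no pooling across experiments) because screening conditions vary
#' between replicates; pass `pool = TRUE` to aggregate. No statistical test
#' is attached — the tallies are descriptive.
#'
#' @param records Data frame with columns `strain`, `experiment_id`,
#'   `colony_id`, `outgrowth` (logical), `morphotype_class` (one of
#'   `"mut-swrA"`, `"mut-comP"`, `"mut-unk"`, `"none"`). The class must be
#'   `"none"` exactly for the rows with `outgrowth = FALSE`.
#' @param pool Aggregate across experiments (default `FALSE`).
#' @return Data frame with one row per strain (x experiment unless pooled):
#'   `strain`, `experiment_id` (absent when pooled), `n_screened`,
#'   `n_outgrowth`, `frequency`, and one `n_<class>` column per morphotype
#'   class observed.
#' @export
tally_outgrowths <- function(records, pool = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("strain", "experiment_id", "outgrowth",
                  "morphotype_class") %in% names(records)))
  bad <- xor(records$outgrowth, records$morphotype_class != "none")
  if (any(bad))
    stop("invalid records: morphotype_class must be 'none' iff outgrowth ",
         "is FALSE (", sum(bad), " offending rows)")
  keys <- if (pool) list(strain = records$strain)
          else list(strain = records$strain,
                    experiment_id = records$experiment_id)
  classes <- setdiff(sort(unique(records$morphotype_class)), "none")
  agg <- aggregate(records$outgrowth, by = keys, FUN = length)
  names(agg)[ncol(agg)] <- "n_screened"
  agg$n_outgrowth <- aggregate(records$outgrowth, by = keys, FUN = sum)$x
  agg$frequency <- agg$n_outgrowth / agg$n_screened
  for (cl in classes) {
    agg[[paste0("n_", gsub("-", "_", cl))]] <-
      aggregate(records$morphotype_class == cl, by = keys, FUN = sum)$x
  }
  agg[order(agg$strain), , drop = FALSE]
}
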