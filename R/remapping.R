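# Remapping analysis.
#
# Remapping between task conditions is detected as a loss of correlation in
# the pairwise rate-map-similarity structure: for every pair of
# simultaneously recorded neurons, the Pearson similarity of their rate
# maps is computed within each condition, and the stability of these
# pair-similarity vectors is compared within versus across conditions.

#' Similarity of two firing rate maps
#'
#' Pearson correlation of the smoothed rates over bins valid in both maps.
#'
#' @param a,b `rate_map` objects on congruent grids.
#' @return Correlation coefficient, or `NA` if fewer than 3 common bins.
#' @export
map_similarity <- function(a, b) {
  stopifnot(inherits(a, "rate_map"), inherits(b, "rate_map"))
  if (!identical(dim(a$rate), dim(b$rate)))
    stop("maps must share the same grid")
  ok <- is.finite(a$rate) & is.finite(b$rate)
  if (sum(ok) < 3) return(NA_real_)
  va <- a$rate[ok]; vb <- b$rate[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Pairwise rate-map similarity within a condition
#'
#' @param maps Named list of `rate_map` objects, one per neuron (>= 2).
#' @param condition Optional condition label stored with the result.
#' @return Data frame with one row per unordered neuron pair: `neuron_a`,
#'   `neuron_b`, `similarity`.
#' @export
pair_similarity <- function(maps, condition = NA_character_) {
  ids <- names(maps)
  if (length(maps) < 2) stop("need at least 2 neurons with valid maps")
  pairs <- utils::combn(seq_along(maps), 2)
  data.frame(condition = condition,
             neuron_a = ids[pairs[1, ]], neuron_b = ids[pairs[2, ]],
             similarity = apply(pairs, 2, function(p)
               map_similarity(maps[[p[1]]], maps[[p[2]]])))
}

#' Stability of pair similarity across conditions
#'
#' Pearson correlation between two pair-similarity vectors over the cell
#' pairs defined (finite) in both conditions. Results based on fewer than
#' `min_pairs` shared pairs are flagged `excluded`.
#'
#' @param vec_a,vec_b Outputs of [pair_similarity()].
#' @param min_pairs Minimum shared pairs (default 10).
#' @return List with `r`, `n_pairs`, and `excluded`.
#' @export
stability <- function(vec_a, vec_b, min_pairs = 10) {
  key <- function(v) paste(v$neuron_a, v$neuron_b)
  m <- match(key(vec_a), key(vec_b))
  ok <- !is.na(m) & is.finite(vec_a$similarity) &
    is.finite(vec_b$similarity[m])
  n <- sum(ok)
  r <- if (n >= 3) stats::cor(vec_a$similarity[ok], vec_b$similarity[m][ok])
       else NA_real_
  list(r = r, n_pairs = n, excluded = n < min_pairs)
}

#' Partition a session into condition-labeled position subsets
#'
#' Builds the position subsets used by the remapping analysis: `A1`/`A2`
#' (odd/even task trials, all on-arena samples), the four
#' search/homing-by-light/dark conditions `SL`, `SD`, `HL`, `HD` restricted
#' to a zone between the bridge and the arena center, their odd/even trial
#' splits (`SL1`, `SL2`, ...), and, when the session metadata records a
#' random-foraging epoch (`rf_start`, `rf_end`), its temporal halves
#' `RF1`/`RF2` and the whole epoch `RF`.
#'
#' @param session A `homing_session`.
#' @param trials,journeys Outputs of [segment_trials()]/[segment_journeys()];
#'   computed if missing.
#' @param zone Rectangle `c(xmin, xmax, ymin, ymax)` for the four
#'   behavioral conditions (default `c(-15, 15, -40, 0)`).
#' @return Named list of position data frames; conditions with no data are
#'   omitted.
#' @export
condition_partition <- function(session, trials = NULL, journeys = NULL,
                                zone = c(-15, 15, -40, 0)) {
  if (is.null(trials)) trials <- segment_trials(session)
  if (is.null(journeys)) journeys <- segment_journeys(session, trials)
  g <- session$geometry
  p <- session$positions
  out <- list()
  use <- trials[!trials$excluded, , drop = FALSE]
  on_arena <- function(q) q[sqrt(q$x^2 + q$y^2) <= g$arena_radius, , drop = FALSE]
  trial_samples <- function(ids) {
    sel <- rep(FALSE, nrow(p))
    for (k in which(use$trial_id %in% ids))
      sel <- sel | (p$t >= use$t_start[k] & p$t <= use$t_end[k])
    on_arena(p[sel, , drop = FALSE])
  }
  odd <- use$trial_id[seq_len(nrow(use)) %% 2 == 1]
  even <- use$trial_id[seq_len(nrow(use)) %% 2 == 0]
  out$A1 <- trial_samples(odd)
  out$A2 <- trial_samples(even)
  in_zone <- function(q)
    q[q$x >= zone[1] & q$x <= zone[2] & q$y >= zone[3] & q$y <= zone[4], ,
      drop = FALSE]
  jp <- journeys[journeys$lever_pressed & journeys$complete, , drop = FALSE]
  jp <- jp[jp$trial_id %in% use$trial_id, , drop = FALSE]
  seg_samples <- function(j, t0, t1) {
    sel <- rep(FALSE, nrow(p))
    for (k in seq_len(nrow(j)))
      sel <- sel | (p$t >= t0[k] & p$t <= t1[k])
    in_zone(p[sel, , drop = FALSE])
  }
  conds <- list(SL = c("search", TRUE), SD = c("search", FALSE),
                HL = c("homing", TRUE), HD = c("homing", FALSE))
  for (lbl in names(conds)) {
    segm <- conds[[lbl]][1]
    lt <- as.logical(conds[[lbl]][2])
    ids <- use$trial_id[use$light == lt]
    jj <- jp[jp$trial_id %in% ids, , drop = FALSE]
    if (!nrow(jj)) next
    t0 <- if (segm == "search") jj$search_start else jj$homing_start
    t1 <- if (segm == "search") jj$search_end else jj$homing_end
    keep <- !is.na(t0) & !is.na(t1)
    jj <- jj[keep, , drop = FALSE]; t0 <- t0[keep]; t1 <- t1[keep]
    if (!nrow(jj)) next
    out[[lbl]] <- seg_samples(jj, t0, t1)
    for (half in 1:2) {
      sub <- seq_len(nrow(jj)) %% 2 == (half %% 2)
      if (any(sub))
        out[[paste0(lbl, half)]] <- seg_samples(jj[sub, , drop = FALSE],
                                                t0[sub], t1[sub])
    }
  }
  md <- session$metadata
  if (!is.null(md$rf_start) && !is.null(md$rf_end)) {
    rf <- p[p$t >= md$rf_start & p$t <= md$rf_end, , drop = FALSE]
    if (nrow(rf)) {
      mid <- (md$rf_start + md$rf_end) / 2
      out$RF <- on_arena(rf)
      out$RF1 <- on_arena(rf[rf$t < mid, , drop = FALSE])
      out$RF2 <- on_arena(rf[rf$t >= mid, , drop = FALSE])
    }
  }
  out[vapply(out, nrow, integer(1)) > 0]
}

#' Rate maps for every neuron in each condition subset
#'
#' @param session A `homing_session`.
#' @param parts Output of [condition_partition()] (or any named list of
#'   position subsets).
#' @param bin_size,smoothing_sd Map parameters (defaults 2.5 cm / 5 cm, the
#'   zone-map convention).
#' @param xlim,ylim Common map extent; defaults to the arena square.
#' @return Nested list: `maps[[condition]][[neuron_id]]` of `rate_map`s.
#' @export
condition_maps <- function(session, parts, bin_size = 2.5, smoothing_sd = 5,
                           xlim = NULL, ylim = NULL) {
  R <- session$geometry$arena_radius
  if (is.null(xlim)) xlim <- c(-R, R)
  if (is.null(ylim)) ylim <- c(-R, R)
  lapply(parts, function(pp)
    lapply(session$spikes, function(st)
      rate_map_2d(pp, st, bin_size = bin_size, smoothing_sd = smoothing_sd,
                  xlim = xlim, ylim = ylim)))
}
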