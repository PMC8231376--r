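#' Code informative SNP calls by parental origin
#'
#' Converts a filtered, informative call table (parents homozygous for
#' different alleles, F1 heterozygous) into the 0/1/2 coding used by the
#' mapping functions: 0 = P1-type homozygote, 1 = heterozygote, 2 = P2-type
#' homozygote, `NA` = missing.
#'
#' @param snps A [snp_table()] that has passed [apply_genotype_filter()].
#' @param p1,p2 Parent sample ids.
#' @param f2_samples F2 sample ids (default: ids starting with `"F2"`).
#' @return List with `geno` (integer matrix markers x individuals, rownames
#'   = marker ids) and `markers` (tibble `marker_id`, `scaffold_id`, `pos`).
#' @export
code_genotypes <- function(snps, p1 = "P1", p2 = "P2", f2_samples = NULL) {
  samples <- snp_samples(snps)
  if (is.null(f2_samples)) f2_samples <- grep("^F2", samples, value = TRUE)
  g1 <- snps$gt[, p1]
  sub <- snps$gt[, f2_samples, drop = FALSE]
  geno <- matrix(NA_integer_, nrow(sub), ncol(sub),
                 dimnames = list(NULL, colnames(sub)))
  geno[sub == "AB"] <- 1L
  p1_mat <- matrix(g1, nrow(sub), ncol(sub))
  geno[!is.na(sub) & sub == p1_mat] <- 0L
  geno[!is.na(sub) & sub != p1_mat & sub != "AB"] <- 2L
  ids <- if ("marker_id" %in% names(snps)) snps$marker_id else
    paste0(snps$scaffold_id, ":", snps$pos)
  rownames(geno) <- ids
  list(geno = geno,
       markers = tibble(marker_id = ids, scaffold_id = snps$scaffold_id,
                        pos = snps$pos))
}

#' Pairwise recombination fractions and LOD for F2 codominant markers
#'
#' Maximum-likelihood estimation by EM over the phase ambiguity of double
#' heterozygotes. For a marker pair, genotype combinations determine the
#' number of recombinant gametes exactly except for the double heterozygote,
#' which mixes 0 and 2 recombinant gametes with posterior weight
#' `r^2 / (r^2 + (1-r)^2)` on the recombinant configuration. The estimate is
#' constrained to \[0, 0.5\] and `LOD = log10 L(r) / L(0.5)` under the
#' 9-class multinomial likelihood. Missing calls are pairwise-deleted.
#'
#' @param geno Integer matrix (markers x individuals), values 0/1/2/`NA`.
#' @param tol,max_iter EM convergence controls.
#' @return List of square matrices `rf`, `lod`, `n` (informative pairs);
#'   pairs with no overlapping calls are `NA`.
#' @export
rf_matrix <- function(geno, tol = 1e-8, max_iter = 100) {
  I0 <- (!is.na(geno) & geno == 0L) * 1
  I1 <- (!is.na(geno) & geno == 1L) * 1
  I2 <- (!is.na(geno) & geno == 2L) * 1
  N00 <- tcrossprod(I0); N01 <- tcrossprod(I0, I1); N02 <- tcrossprod(I0, I2)
  N10 <- tcrossprod(I1, I0); N11 <- tcrossprod(I1); N12 <- tcrossprod(I1, I2)
  N20 <- tcrossprod(I2, I0); N21 <- tcrossprod(I2, I1); N22 <- tcrossprod(I2)
  ntot <- N00 + N01 + N02 + N10 + N11 + N12 + N20 + N21 + N22
  r_fixed <- N01 + N10 + N12 + N21 + 2 * (N02 + N20)

  r <- matrix(0.25, nrow(ntot), ncol(ntot))
  denom <- 2 * pmax(ntot, 1)
  for (it in seq_len(max_iter)) {
    w <- r^2 / (r^2 + (1 - r)^2)
    r_new <- (r_fixed + 2 * N11 * w) / denom
    r_new <- pmin(pmax(r_new, 1e-9), 0.5)
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }

  lod <- lod_from_counts(r, N00, N01, N02, N10, N11, N12, N20, N21, N22)
  empty <- ntot == 0
  r[empty] <- NA_real_
  lod[empty] <- NA_real_
  diag(r) <- 0
  dimnames(r) <- dimnames(lod) <- dimnames(ntot) <-
    list(rownames(geno), rownames(geno))
  list(rf = r, lod = lod, n = ntot)
}

# internal: multinomial LOD of r against r = 0.5 given 9-class counts
lod_from_counts <- function(r, N00, N01, N02, N10, N11, N12, N20, N21, N22) {
  l10 <- function(p, p0, n) n * log10(pmax(p, 1e-300) / p0)
  q <- 1 - r
  l10(q^2 / 4, 1 / 16, N00) + l10(r * q / 2, 1 / 8, N01) + l10(r^2 / 4, 1 / 16, N02) +
    l10(r * q / 2, 1 / 8, N10) + l10((q^2 + r^2) / 2, 1 / 4, N11) + l10(r * q / 2, 1 / 8, N12) +
    l10(r^2 / 4, 1 / 16, N20) + l10(r * q / 2, 1 / 8, N21) + l10(q^2 / 4, 1 / 16, N22)
}

#' Recombination fraction between two call vectors
#'
#' @param calls_a,calls_b Integer vectors coded 0/1/2/`NA`.
#' @inheritParams rf_matrix
#' @return List with `rf`, `lod` and `n` (number of informative pairs);
#'   `rf` is `NA` when no individual carries both calls.
#' @export
estimate_rf <- function(calls_a, calls_b, tol = 1e-8, max_iter = 100) {
  stopifnot(length(calls_a) == length(calls_b))
  m <- rbind(a = calls_a, b = calls_b)
  res <- rf_matrix(m, tol = tol, max_iter = max_iter)
  list(rf = res$rf["a", "b"], lod = res$lod["a", "b"], n = res$n["a", "b"])
}

#' Group markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with
#' `rf <= max_rf` and `LOD >= min_lod`. Groups are named `LG1`, `LG2`, ...
#' in descending order of marker count (ties broken by smallest member
#' index for determinism).
#'
#' @param rfm Output of [rf_matrix()].
#' @param max_rf Maximum recombination fraction for linkage (default 0.35).
#' @param min_lod Minimum LOD for linkage (default 6).
#' @return Tibble with `marker_id`, `lg` (`"LG1"`, ...), `lg_index`.
#' @export
group_markers <- function(rfm, max_rf = 0.35, min_lod = 6) {
  adj <- !is.na(rfm$rf) & !is.na(rfm$lod) & rfm$rf <= max_rf & rfm$lod >= min_lod
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- tabulate(comp$membership)
  first_member <- vapply(seq_along(sizes),
                         function(k) min(which(comp$membership == k)), integer(1))
  rank <- order(-sizes, first_member)
  lg_index <- match(comp$membership, rank)
  ids <- rownames(rfm$rf) %||% as.character(seq_along(comp$membership))
  tibble(marker_id = ids, lg = paste0("LG", lg_index), lg_index = lg_index)
}

#' Order markers within a linkage group
#'
#' Greedy nearest-neighbour chaining seeded at the highest-LOD pair,
#' refined by 2-opt moves until the sum of adjacent recombination fractions
#' stops decreasing. The output orientation is canonical: the first marker
#' id sorts lexicographically before the last.
#'
#' @param marker_ids Markers in the group.
#' @param rfm Output of [rf_matrix()] covering the group.
#' @return Character vector: the ordered marker ids.
#' @export
order_markers <- function(marker_ids, rfm) {
  m <- length(marker_ids)
  if (m <= 2) return(canonical_orientation(marker_ids))
  D <- rfm$rf[marker_ids, marker_ids]
  D[is.na(D)] <- 0.5
  L <- rfm$lod[marker_ids, marker_ids]
  L[is.na(L)] <- -Inf
  diag(L) <- -Inf

  # seed: the two most strongly linked markers
  seed <- arrayInd(which.max(L), dim(L))
  path <- c(seed[1], seed[2])
  free <- setdiff(seq_len(m), path)
  while (length(free) > 0) {
    d_head <- D[path[1], free]
    d_tail <- D[path[length(path)], free]
    if (min(d_head) <= min(d_tail)) {
      pick <- free[which.min(d_head)]
      path <- c(pick, path)
    } else {
      pick <- free[which.min(d_tail)]
      path <- c(path, pick)
    }
    free <- setdiff(free, pick)
  }

  path <- two_opt(path, D)
  canonical_orientation(marker_ids[path])
}

# internal: 2-opt refinement of a path minimising the sum of adjacent
# distances; best-improvement moves, vectorised delta evaluation.
two_opt <- function(path, D, max_moves = 20000) {
  m <- length(path)
  if (m < 3) return(path)
  for (move in seq_len(max_moves)) {
    # interior reversals i..j with 2 <= i <= j <= m-1
    ii <- 2:(m - 1)
    Pp <- D[path[ii - 1], path[ii], drop = FALSE]  # [a,b] = d(p[i-1], p[j])
    Nn <- D[path[ii], path[ii + 1], drop = FALSE]  # [a,b] = d(p[i], p[j+1])
    cur_left <- D[cbind(path[ii - 1], path[ii])]   # d(p[i-1], p[i])
    cur_right <- D[cbind(path[ii], path[ii + 1])]  # d(p[j], p[j+1])
    # delta[a,b] = d(p[i-1],p[j]) + d(p[i],p[j+1]) - d(p[i-1],p[i]) - d(p[j],p[j+1])
    delta <- sweep(sweep(Pp + Nn, 1, cur_left), 2, cur_right)
    delta[row(delta) > col(delta)] <- Inf  # keep i <= j only

    # prefix reversals (1..j), j = 1..m-1: only edge (j, j+1) changes
    jj <- 1:(m - 1)
    d_pref <- D[cbind(path[1], path[jj + 1])] - D[cbind(path[jj], path[jj + 1])]
    # suffix reversals (i..m), i = 2..m: only edge (i-1, i) changes
    kk <- 2:m
    d_suf <- D[cbind(path[kk - 1], path[m])] - D[cbind(path[kk - 1], path[kk])]

    best_int <- which.min(delta)
    cand <- c(min(delta), min(d_pref), min(d_suf))
    if (min(cand) >= -1e-12) break
    which_best <- which.min(cand)
    if (which_best == 1) {
      ind <- arrayInd(best_int, dim(delta))
      i <- ii[ind[1]]; j <- ii[ind[2]]
      path[i:j] <- rev(path[i:j])
    } else if (which_best == 2) {
      j <- jj[which.min(d_pref)]
      path[1:j] <- rev(path[1:j])
    } else {
      i <- kk[which.min(d_suf)]
      path[i:m] <- rev(path[i:m])
    }
  }
  path
}

canonical_orientation <- function(ids) {
  if (length(ids) > 1 && ids[length(ids)] < ids[1]) rev(ids) else ids
}

#' Convert recombination fractions to map distances
#'
#' Haldane: `d = -50 ln(1 - 2r)` (no crossover interference);
#' Kosambi: `d = 25 ln((1 + 2r) / (1 - 2r))` (partial interference).
#'
#' @param rf Adjacent-interval recombination fractions in `[0, 0.5)`.
#' @param map_function `"kosambi"` (default, common for plant maps) or
#'   `"haldane"`.
#' @return Cumulative cM positions starting at 0, length `length(rf) + 1`.
#' @export
#' @examples
#' map_distances(c(0.1, 0.1), "haldane")   # 0, 11.157, 22.314
map_distances <- function(rf, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (length(rf) == 0) return(0)
  if (any(rf >= 0.5 | rf < 0)) {
    abort("adjacent recombination fractions must lie in [0, 0.5): ordering invalid",
          class = "radanchor_input_error")
  }
  d <- switch(map_function,
    haldane = -50 * log(1 - 2 * rf),
    kosambi = 25 * log((1 + 2 * rf) / (1 - 2 * rf))
  )
  c(0, cumsum(d))
}

#' Prune singleton double recombinants
#'
#' A call that disagrees with both of its (identical) immediate neighbours
#' along an ordered chromosome implies two crossovers within a short
#' interval and is far more likely a genotyping error; such calls are set
#' missing. This is the usual light-touch error correction applied before
#' map-distance estimation, without which per-interval error inflates the
#' map length by roughly twice the error rate per interval.
#'
#' @param geno_ordered Coded genotype matrix with rows in map order.
#' @return The matrix with singleton double recombinants set `NA`.
#' @export
prune_singletons <- function(geno_ordered) {
  m <- nrow(geno_ordered)
  if (m < 3) return(geno_ordered)
  for (j in seq_len(ncol(geno_ordered))) {
    v <- geno_ordered[, j]
    idx <- which(!is.na(v))            # neighbours skip missing calls
    if (length(idx) < 3) next
    x <- v[idx]
    k <- 2:(length(x) - 1)
    bad <- x[k] != x[k - 1] & x[k] != x[k + 1] & x[k - 1] == x[k + 1]
    if (any(bad)) geno_ordered[idx[k][bad], j] <- NA_integer_
  }
  geno_ordered
}

#' Build an F2 genetic map
#'
#' Runs the full mapping chain: pairwise recombination fractions and LOD
#' ([rf_matrix()]), single-linkage grouping ([group_markers()]),
#' within-group ordering ([order_markers()]), optional singleton
#' double-recombinant pruning ([prune_singletons()]) and cM positions from
#' adjacent-interval recombination fractions ([map_distances()]). Adjacent
#' recombination fractions at or above 0.5 (possible in noisy data) are
#' clamped just below 0.5 with a warning.
#'
#' @param geno Integer marker matrix as from [code_genotypes()].
#' @param markers Tibble with `marker_id`, `scaffold_id`, `pos` matching
#'   `geno` rownames.
#' @param error_prune Prune singleton double recombinants before distance
#'   estimation (default `TRUE`).
#' @inheritParams group_markers
#' @inheritParams map_distances
#' @return A tibble of class `"genetic_map"`: `marker_id`, `scaffold_id`,
#'   `pos`, `lg`, `lg_index`, `order`, `cm`, with attributes
#'   `map_function` and `n_individuals`.
#' @export
build_linkage_map <- function(geno, markers, max_rf = 0.35, min_lod = 6,
                              map_function = c("kosambi", "haldane"),
                              error_prune = TRUE) {
  map_function <- match.arg(map_function)
  stopifnot(identical(rownames(geno), markers$marker_id))
  rfm <- rf_matrix(geno)
  groups <- group_markers(rfm, max_rf = max_rf, min_lod = min_lod)

  out <- purrr::map(sort(unique(groups$lg_index)), function(k) {
    ids <- groups$marker_id[groups$lg_index == k]
    ord <- order_markers(ids, rfm)
    if (length(ord) > 1) {
      sub <- geno[ord, , drop = FALSE]
      if (error_prune) sub <- prune_singletons(sub)
      adj <- vapply(seq_len(nrow(sub) - 1), function(i) {
        estimate_rf(sub[i, ], sub[i + 1, ])$rf
      }, numeric(1))
    } else adj <- numeric(0)
    adj[is.na(adj)] <- 0.4999
    if (any(adj >= 0.5)) {
      warn(sprintf("LG%d: clamping %d adjacent rf value(s) >= 0.5", k, sum(adj >= 0.5)))
      adj <- pmin(adj, 0.4999)
    }
    cm <- map_distances(adj, map_function)
    tibble(marker_id = ord, lg = paste0("LG", k), lg_index = k,
           order = seq_along(ord), cm = cm)
  }) |> purrr::list_rbind()

  out <- left_join(out, markers, by = "marker_id") |>
    select("marker_id", "scaffold_id", "pos", "lg", "lg_index", "order", "cm")
  structure(out, class = c("genetic_map", class(out)),
            map_function = map_function, n_individuals = ncol(geno))
}

#' Per-group summary of a genetic map
#'
#' @param map A `"genetic_map"` from [build_linkage_map()] (or any tibble
#'   with `lg`, `lg_index`, `cm`).
#' @return Tibble with one row per linkage group: `lg`, `n_markers`,
#'   `length_cm`, `largest_gap_cm` (0 for single-marker groups).
#' @export
map_summary <- function(map) {
  as_tibble(map) |>
    group_by(.data$lg, .data$lg_index) |>
    summarise(
      n_markers = n(),
      length_cm = max(.data$cm) - min(.data$cm),
      largest_gap_cm = if (n() > 1) max(diff(sort(.data$cm))) else 0,
      .groups = "drop"
    ) |>
    arrange(.data$lg_index) |>
    select(-"lg_index")
}

#' @method tidy genetic_map
#' @export
tidy.genetic_map <- function(x, ...) as_tibble(x)

#' @method glance genetic_map
#' @export
glance.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  gap_lg <- s$lg[which.max(s$largest_gap_cm)]
  tibble(n_groups = nrow(s), n_markers = sum(s$n_markers),
         total_cm = sum(s$length_cm),
         largest_gap_cm = max(s$largest_gap_cm), largest_gap_lg = gap_lg,
         map_function = attr(x, "map_function"))
}

#' @export
print.genetic_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<genetic_map> %d markers in %d linkage groups, %.1f cM total (%s)\n",
              g$n_markers, g$n_groups, g$total_cm, g$map_function))
  print(map_summary(x))
  invisible(x)
}

#' @method autoplot genetic_map
#' @export
autoplot.genetic_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$lg, y = .data$cm)) +
    geom_segment(aes(x = as.numeric(factor(.data$lg, unique(.data$lg))) - 0.2,
                     xend = as.numeric(factor(.data$lg, unique(.data$lg))) + 0.2,
                     yend = .data$cm), linewidth = 0.2) +
    scale_y_reverse() +
    labs(x = "linkage group", y = "position (cM)") +
    theme_minimal()
}

#' Recombination-fraction heatmap for an ordered map
#'
#' The classic map-verification plot: pairwise recombination fractions of
#' the markers in map order; a clean map shows a low-rf band along the
#' diagonal within each linkage group.
#'
#' @param map A `"genetic_map"`.
#' @param rfm Output of [rf_matrix()] covering the map's markers.
#' @return A ggplot object.
#' @export
plot_rf_heatmap <- function(map, rfm) {
  ord <- map$marker_id
  sub <- rfm$rf[ord, ord]
  df <- tibble(
    a = rep(seq_along(ord), times = length(ord)),
    b = rep(seq_along(ord), each = length(ord)),
    rf = as.vector(sub)
  )
  ggplot(df, aes(.data$a, .data$b, fill = .data$rf)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90", limits = c(0, 0.5)) +
    coord_fixed() +
    labs(x = "marker (map order)", y = "marker (map order)", fill = "rf") +
    theme_minimal()
}
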