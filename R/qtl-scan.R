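#' F2 genotype transition matrix between two loci
#'
#' No-interference model: the two homologues recombine independently with
#' probability `r`, giving the classic 3x3 genotype transition matrix used
#' for conditional genotype probabilities along an F2 chromosome.
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return 3x3 matrix, rows = genotype at the first locus (0, 1, 2 copies of
#'   the P2 allele), columns = genotype at the second.
#' @keywords internal
trans_f2 <- function(r) {
  q <- 1 - r
  matrix(c(q^2,     2 * r * q,   r^2,
           r * q,   q^2 + r^2,   r * q,
           r^2,     2 * r * q,   q^2),
         3, 3, byrow = TRUE)
}

# inverse map functions: cM distance -> recombination fraction
inv_map_function <- function(d_cm, map_function) {
  switch(map_function,
    haldane = 0.5 * (1 - exp(-2 * d_cm / 100)),
    kosambi = 0.5 * tanh(2 * d_cm / 100)
  )
}

#' Conditional genotype probabilities on a cM grid
#'
#' At each grid point, P(AA/AB/BB) for every individual given the nearest
#' non-missing flanking marker genotypes, under the no-interference model
#' with the map's own map function. At a typed marker with a non-missing
#' call the distribution is degenerate. The grid contains every marker
#' position plus, when `step_cm > 0`, intermediate points every `step_cm`
#' cM.
#'
#' @param map A `"genetic_map"` from [build_linkage_map()].
#' @param geno Coded genotype matrix (markers x individuals) as from
#'   [code_genotypes()]; rownames must cover the map's markers.
#' @param step_cm Grid step in cM; 0 places points only at markers.
#' @return List of class `"qtl_genoprob"`: `grid` (tibble `lg`, `lg_index`,
#'   `cm`, `marker_id` — `NA` for pure grid points), `prob` (array
#'   individuals x points x 3), `individuals`, `map_function`.
#' @export
genotype_probs <- function(map, geno, step_cm = 1) {
  df <- as_tibble(map)
  if (nrow(df) == 0) abort("empty map", class = "radanchor_input_error")
  map_function <- attr(map, "map_function") %||% "kosambi"
  individuals <- colnames(geno)
  n <- length(individuals)
  prior <- c(0.25, 0.5, 0.25)

  grids <- list()
  probs <- list()
  for (k in sort(unique(df$lg_index))) {
    mk <- df |> filter(.data$lg_index == k) |> arrange(.data$cm)
    g_cm <- if (step_cm > 0) {
      sort(unique(c(mk$cm, seq(min(mk$cm), max(mk$cm), by = step_cm))))
    } else sort(unique(mk$cm))
    at_marker <- match(round(g_cm, 9), round(mk$cm, 9))  # first marker at that cm
    grids[[length(grids) + 1]] <- tibble(
      lg = paste0("LG", k), lg_index = k, cm = g_cm,
      marker_id = mk$marker_id[at_marker]
    )
    P <- array(NA_real_, c(n, length(g_cm), 3))
    gk <- geno[mk$marker_id, , drop = FALSE]
    for (ind in seq_len(n)) {
      calls <- gk[, ind]
      known <- which(!is.na(calls))
      if (length(known) == 0) {
        P[ind, , ] <- matrix(prior, length(g_cm), 3, byrow = TRUE)
        next
      }
      kcm <- mk$cm[known]
      kg <- calls[known] + 1L
      li <- findInterval(g_cm, kcm)            # nearest known marker at/left
      ri <- length(kcm) - findInterval(-g_cm, rev(-kcm)) + 1  # at/right
      for (j in seq_along(g_cm)) {
        l <- li[j]; r <- ri[j]
        if (l >= 1 && kcm[l] == g_cm[j]) {      # typed, non-missing call
          v <- c(0, 0, 0); v[kg[l]] <- 1
        } else {
          w <- rep(1, 3)
          if (l >= 1) {
            Tl <- trans_f2(inv_map_function(g_cm[j] - kcm[l], map_function))
            w <- w * Tl[kg[l], ]
          } else {
            w <- w * prior
          }
          if (r <= length(kcm)) {
            Tr <- trans_f2(inv_map_function(kcm[r] - g_cm[j], map_function))
            w <- w * Tr[, kg[r]]
          }
          v <- w / sum(w)
        }
        P[ind, j, ] <- v
      }
    }
    probs[[length(probs) + 1]] <- P
  }
  grid <- purrr::list_rbind(grids)
  prob <- array(NA_real_, c(n, nrow(grid), 3))
  off <- 0
  for (P in probs) {
    prob[, off + seq_len(dim(P)[2]), ] <- P
    off <- off + dim(P)[2]
  }
  structure(list(grid = grid, prob = prob, individuals = individuals,
                 map_function = map_function),
            class = "qtl_genoprob")
}

#' Genome scan by Haley-Knott regression
#'
#' At every grid point the phenotype is regressed on the expected additive
#' score `P(BB) - P(AA)` and dominance score `P(AB)`;
#' `LOD = (n/2) log10(RSS0 / RSS1)`. In composite mode (`"cim"`) marker
#' cofactors are first forward-selected by BIC (up to `n_cofactors`), and at
#' each test position any cofactor within `window_cm` of the position on the
#' same linkage group is excluded from both null and full models. A binary
#' 0/1 trait is analysed by the same linear regression (a linear-probability
#' approximation).
#'
#' @param probs A `"qtl_genoprob"` from [genotype_probs()].
#' @param phenotypes Data frame with an `individual` column and the trait
#'   column, or a numeric vector named by individual.
#' @param trait Trait column name (when `phenotypes` is a data frame).
#' @param method `"hk"` (interval mapping) or `"cim"` (composite).
#' @param geno Marker genotype matrix, required for `"cim"` cofactor
#'   selection.
#' @param map The `"genetic_map"`, required for `"cim"` (cofactor
#'   positions).
#' @param n_cofactors Maximum cofactors in composite mode (default 5).
#' @param window_cm Cofactor exclusion window around the test position
#'   (default 10).
#' @return A tibble of class `"qtl_scan"`: `lg`, `lg_index`, `cm`,
#'   `marker_id`, `lod`, with attributes `n`, `trait`, `method`.
#' @export
scan_qtl <- function(probs, phenotypes, trait = "bolting",
                     method = c("hk", "cim"), geno = NULL, map = NULL,
                     n_cofactors = 5, window_cm = 10) {
  method <- match.arg(method)
  y <- extract_trait(phenotypes, trait, probs$individuals)
  if (sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    abort("constant phenotype", class = "radanchor_input_error")
  }
  use <- !is.na(y)
  y <- y[use]
  n <- length(y)
  a_sc <- (probs$prob[use, , 3] - probs$prob[use, , 1])
  d_sc <- probs$prob[use, , 2]

  cof <- NULL
  if (method == "cim") {
    if (is.null(geno) || is.null(map)) {
      abort("composite mode needs `geno` and `map` for cofactor selection",
            class = "radanchor_input_error")
    }
    cof <- select_cofactors(y, geno[, probs$individuals[use], drop = FALSE],
                            map, n_cofactors)
  }

  lod <- vapply(seq_len(nrow(probs$grid)), function(j) {
    X1 <- cbind(1, a_sc[, j], d_sc[, j])
    X0 <- matrix(1, n, 1)
    if (!is.null(cof) && nrow(cof$info) > 0) {
      keep <- !(cof$info$lg_index == probs$grid$lg_index[j] &
                  abs(cof$info$cm - probs$grid$cm[j]) < window_cm)
      if (any(keep)) {
        Z <- cof$scores[, as.vector(rbind(2 * which(keep) - 1, 2 * which(keep))), drop = FALSE]
        X1 <- cbind(X1, Z)
        X0 <- cbind(X0, Z)
      }
    }
    rss1 <- rss_of(X1, y)
    rss0 <- rss_of(X0, y)
    (n / 2) * log10(rss0 / max(rss1, rss0 * 1e-12))
  }, numeric(1))

  out <- probs$grid
  out$lod <- pmax(lod, 0)
  structure(out, class = c("qtl_scan", class(out)),
            n = n, trait = trait, method = method)
}

# internal: residual sum of squares of y on design X
rss_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

extract_trait <- function(phenotypes, trait, individuals) {
  if (is.data.frame(phenotypes)) {
    stopifnot("individual" %in% names(phenotypes), trait %in% names(phenotypes))
    idx <- match(individuals, phenotypes$individual)
    as.numeric(phenotypes[[trait]][idx])
  } else {
    if (!is.null(names(phenotypes))) as.numeric(phenotypes[individuals])
    else as.numeric(phenotypes)
  }
}

# internal: forward selection of marker cofactors by BIC.
# markers are scored as additive (g - 1) and dominance (g == 1) columns with
# mean imputation of missing calls.
select_cofactors <- function(y, geno, map, n_cofactors) {
  df <- as_tibble(map)
  ids <- intersect(df$marker_id, rownames(geno))
  g <- geno[ids, , drop = FALSE]
  a <- t(g) - 1
  d <- t(g == 1L) * 1
  imp <- function(m) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 2]]
    m
  }
  a <- imp(a); d <- imp(d)
  n <- length(y)
  chosen <- integer(0)
  X <- matrix(1, n, 1)
  bic <- n * log(rss_of(X, y) / n) + log(n) * ncol(X)
  repeat {
    if (length(chosen) >= n_cofactors) break
    cand <- setdiff(seq_along(ids), chosen)
    scores <- vapply(cand, function(i) {
      Xi <- cbind(X, a[, i], d[, i])
      n * log(rss_of(Xi, y) / n) + log(n) * ncol(Xi)
    }, numeric(1))
    if (min(scores) >= bic - 1e-9) break
    best <- cand[which.min(scores)]
    chosen <- c(chosen, best)
    X <- cbind(X, a[, best], d[, best])
    bic <- min(scores)
  }
  if (length(chosen) == 0) {
    return(list(info = tibble(marker_id = character(), lg_index = integer(),
                              cm = numeric()),
                scores = matrix(nrow = n, ncol = 0)))
  }
  info <- tibble(marker_id = ids[chosen]) |>
    left_join(df |> select("marker_id", "lg_index", "cm"), by = "marker_id")
  scores <- matrix(nrow = n, ncol = 0)
  for (i in chosen) scores <- cbind(scores, a[, i], d[, i])
  list(info = info, scores = scores)
}

#' Percent variance explained from a single-QTL LOD
#'
#' `PVE = 100 (1 - 10^(-2 LOD / n))` — the variance share implied by the
#' likelihood ratio of a single-locus model. Totals for several QTLs must
#' come from a joint model's residual sums of squares, not from summing
#' single-locus values.
#'
#' @param lod LOD score(s).
#' @param n Number of individuals.
#' @return PVE in percent.
#' @export
#' @examples
#' pve_from_lod(1, 100)   # ~4.5%
pve_from_lod <- function(lod, n) {
  stopifnot(n >= 2)
  100 * (1 - 10^(-2 * lod / n))
}

#' Genome-wide LOD significance threshold by permutation
#'
#' Permutes the phenotype over individuals, rescans, and returns the
#' `1 - alpha` quantile of the genome-wide maximum LOD. Haley-Knott
#' regression is used for the permuted scans.
#'
#' @inheritParams scan_qtl
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return The LOD threshold (type-7 quantile), with the vector of permuted
#'   maxima as attribute `"perm_max"`.
#' @export
permutation_threshold <- function(probs, phenotypes, trait = "bolting",
                                  n_perm = 1000, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 100)
  y <- extract_trait(phenotypes, trait, probs$individuals)
  use <- !is.na(y)
  y <- y[use]
  n <- length(y)
  set.seed(derive_seed(seed, 6L))
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  max_lod <- rep(-Inf, n_perm)
  a_all <- probs$prob[use, , 3] - probs$prob[use, , 1]
  d_all <- probs$prob[use, , 2]
  for (j in seq_len(nrow(probs$grid))) {
    X <- cbind(1, a_all[, j], d_all[, j])
    qx <- qr.Q(qr(X))
    rss1 <- colSums(Y^2) - colSums((t(qx) %*% Y)^2)
    lod <- (n / 2) * log10(rss0 / rss1)
    max_lod <- pmax(max_lod, lod)
  }
  structure(unname(quantile(max_lod, 1 - alpha)), perm_max = max_lod)
}

#' LOD support interval around a scan peak
#'
#' The interval spans the outermost grid positions, within the peak's
#' linkage group, whose LOD is within `drop` of the peak (1.5-LOD support
#' interval by default, a common 95% CI surrogate). Nearest genotyped
#' flanking markers are reported; when an AGP plan is supplied their
#' physical span on the pseudomolecule is added.
#'
#' @param scan A `"qtl_scan"`.
#' @param drop LOD drop defining the interval (default 1.5).
#' @param lg Linkage group to inspect; default the group holding the global
#'   peak (ties resolved toward the widest interval).
#' @param map Optional `"genetic_map"` for flanking-marker coordinates.
#' @param agp Optional AGP tibble for the physical span of the interval.
#' @return One-row tibble: `lg`, `peak_cm`, `peak_lod`, `ci_lo`, `ci_hi`,
#'   `flank_lo`, `flank_hi`, and `physical_span_bp` when computable.
#' @export
lod_support_interval <- function(scan, drop = 1.5, lg = NULL, map = NULL,
                                 agp = NULL) {
  df <- as_tibble(scan)
  if (is.null(lg)) lg <- df$lg[which.max(df$lod)]
  sub <- df |> filter(.data$lg == !!lg)
  peak <- max(sub$lod)
  peak_cm <- sub$cm[which.max(sub$lod)]
  inside <- sub$cm[sub$lod >= peak - drop]
  ci <- c(min(inside), max(inside))
  flank_lo <- flank_hi <- NA_character_
  span <- NA_real_
  typed <- sub |> filter(!is.na(.data$marker_id))
  if (nrow(typed) > 0) {
    lo_c <- typed |> filter(.data$cm <= ci[1])
    hi_c <- typed |> filter(.data$cm >= ci[2])
    flank_lo <- if (nrow(lo_c)) lo_c$marker_id[which.max(lo_c$cm)] else
      typed$marker_id[which.min(typed$cm)]
    flank_hi <- if (nrow(hi_c)) hi_c$marker_id[which.min(hi_c$cm)] else
      typed$marker_id[which.max(typed$cm)]
    if (!is.null(map) && !is.null(agp)) {
      co <- purrr::map_dbl(c(flank_lo, flank_hi), function(id) {
        r <- as_tibble(map) |> filter(.data$marker_id == id)
        if (nrow(r) == 0) return(NA_real_)
        marker_object_coord(agp, r$scaffold_id[1], r$pos[1])
      })
      if (!anyNA(co)) span <- abs(co[2] - co[1]) + 1
    }
  }
  tibble(lg = lg, peak_cm = peak_cm, peak_lod = peak,
         ci_lo = ci[1], ci_hi = ci[2],
         flank_lo = flank_lo, flank_hi = flank_hi,
         physical_span_bp = span)
}

# internal: pseudomolecule coordinate of a scaffold position via the AGP
marker_object_coord <- function(agp, scaffold_id, pos) {
  rows <- agp |> filter(.data$component_type == "W")
  rows <- rows |>
    filter(.data$component_id == scaffold_id,
           as.numeric(.data$component_beg) <= pos,
           as.numeric(.data$component_end) >= pos)
  if (nrow(rows) == 0) return(NA_real_)
  r <- rows[1, ]
  if (r$orientation == "-") {
    r$object_beg + (as.numeric(r$component_end) - pos)
  } else {
    r$object_beg + (pos - as.numeric(r$component_beg))
  }
}

#' Exact Wilcoxon rank-sum test (Mann-Whitney) by enumeration
#'
#' `W` is the Mann-Whitney statistic for the first group (its rank sum minus
#' `n_a (n_a + 1) / 2`, average ranks for ties). The two-sided p-value is
#' exact: the full distribution of `W` over all `choose(n_a + n_b, n_a)`
#' group assignments is enumerated by dynamic programming over (doubled)
#' ranks, and the probability of a deviation from the null mean at least as
#' large as observed is summed. The null distribution is symmetric about
#' `n_a n_b / 2`, also under ties.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return One-row tibble: `W`, `p_value`, `n_a`, `n_b`.
#' @export
#' @examples
#' exact_rank_sum(c(5, 6, 7), c(8, 9, 10))  # complete separation, W = 0
exact_rank_sum <- function(group_a, group_b) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  stopifnot(n_a > 0, n_b > 0)
  r <- rank(c(group_a, group_b))
  r2 <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  # DP over the distribution of doubled rank sums of size-n_a subsets
  max_s <- sum(sort(r2, decreasing = TRUE)[seq_len(n_a)])
  cnt <- matrix(0, n_a + 1, max_s + 1)
  cnt[1, 1] <- 1
  for (x in r2) {
    for (k in rev(seq_len(n_a))) {
      nz <- which(cnt[k, ] > 0)
      tgt <- nz + x
      ok <- tgt <= max_s + 1
      cnt[k + 1, tgt[ok]] <- cnt[k + 1, tgt[ok]] + cnt[k, nz[ok]]
    }
  }
  s2 <- which(cnt[n_a + 1, ] > 0) - 1
  prob <- cnt[n_a + 1, s2 + 1] / sum(cnt[n_a + 1, ])
  w_vals <- s2 / 2 - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  p <- sum(prob[abs(w_vals - mu) >= abs(w_obs - mu) - 1e-9])
  tibble(W = w_obs, p_value = min(1, p), n_a = n_a, n_b = n_b)
}

#' @method tidy qtl_scan
#' @export
tidy.qtl_scan <- function(x, ...) as_tibble(x)

#' @method glance qtl_scan
#' @export
glance.qtl_scan <- function(x, ...) {
  df <- as_tibble(x)
  peak <- df[which.max(df$lod), ]
  tibble(trait = attr(x, "trait"), method = attr(x, "method"),
         n = attr(x, "n"), n_positions = nrow(df),
         peak_lg = peak$lg, peak_cm = peak$cm, peak_lod = peak$lod,
         peak_pve = pve_from_lod(peak$lod, attr(x, "n")))
}

#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(.data$cm, .data$lod)) +
    geom_line() +
    facet_grid(cols = vars(.data$lg), scales = "free_x", space = "free_x") +
    labs(x = "map position (cM)", y = "LOD",
         title = attr(object, "trait")) +
    theme_minimal()
  if (!is.null(threshold)) p <- p + geom_hline(yintercept = threshold,
                                               linetype = "dashed")
  p
}

#' @export
print.qtl_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<qtl_scan> trait '%s' (%s), n = %d: peak LOD %.2f on %s at %.1f cM\n",
              g$trait, g$method, g$n, g$peak_lod, g$peak_lg, g$peak_cm))
  invisible(x)
}
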