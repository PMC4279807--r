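#' Leave-one-out case enumeration: direct registrations
#'
#' All ordered (fixed, moving) pairs of distinct atlas ids: each atlas in
#' turn plays the patient and every other atlas is registered to it. For
#' `n` atlases this yields `n * (n - 1)` cases (90 for 10 atlases).
#'
#' @param n number of atlases, `>= 2`.
#' @return List of cases, each `list(fixed, moving, intermediates =
#'   integer(0))`.
#' @export
enumerate_direct <- function(n) {
  if (n < 2) stop("at least 2 atlases are required")
  out <- vector("list", n * (n - 1))
  idx <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[[idx]] <- list(fixed = i, moving = j, intermediates = integer(0))
    idx <- idx + 1L
  }
  out
}

#' Leave-one-out case enumeration: one intermediate link
#'
#' All ordered triples (fixed `i`, intermediate `k`, moving `j`) of distinct
#' ids: `n * (n - 1) * (n - 2)` cases (720 for 10 atlases).
#'
#' @param n number of atlases, `>= 3`.
#' @return List of cases, each `list(fixed, moving, intermediates)` with one
#'   intermediate.
#' @export
enumerate_one_link <- function(n) {
  if (n < 3) stop("at least 3 atlases are required for one-link chains")
  out <- vector("list", n * (n - 1) * (n - 2))
  idx <- 1L
  for (i in seq_len(n)) for (k in seq_len(n)) for (j in seq_len(n)) {
    if (i == k || i == j || j == k) next
    out[[idx]] <- list(fixed = i, moving = j, intermediates = k)
    idx <- idx + 1L
  }
  out
}

n_distinct_chains <- function(n, l) {
  # ordered selections: fixed, l intermediates, moving, all distinct
  prod(seq(n, n - l - 1))
}

#' Randomly sample linked registration chains
#'
#' Uniform sampling without replacement over all chains (fixed, ordered
#' distinct intermediates of length `l`, moving) with all ids distinct. When
#' fewer than `n_samples` distinct chains exist they are all returned
#' (enumerated exhaustively). A chain of `l` intermediates composes `l + 1`
#' transformations; with `n` atlases at most `n - 2` intermediates are
#' possible (9 composed transformations for 10 atlases).
#'
#' @param n number of atlases.
#' @param l number of intermediates, `0 <= l <= n - 2`.
#' @param n_samples number of chains requested, `>= 1`.
#' @param seed integer seed; the sample is deterministic per seed.
#' @return List of cases `list(fixed, moving, intermediates)`.
#' @export
sample_chains <- function(n, l, n_samples, seed) {
  if (l < 0 || l > n - 2)
    stop(sprintf("l must lie in [0, n - 2]; got l = %d with n = %d", l, n))
  if (n_samples < 1) stop("n_samples must be >= 1")
  total <- n_distinct_chains(n, l)
  if (n_samples >= total && total <= 2e5) {
    if (l == 0) return(enumerate_direct(n))
    if (l == 1) return(enumerate_one_link(n))
    return(enumerate_chains_rec(n, l))
  }
  n_samples <- min(n_samples, total)
  out <- vector("list", n_samples)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  got <- 0L
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  while (got < n_samples) {
    ids <- sample.int(n, l + 2)
    key <- paste(ids, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    out[[got]] <- list(fixed = ids[1],
                       moving = ids[l + 2],
                       intermediates = if (l > 0) ids[2:(l + 1)] else integer(0))
  }
  out
}

enumerate_chains_rec <- function(n, l) {
  out <- list()
  recurse <- function(prefix, remaining, depth) {
    if (depth == l + 2) {
      out[[length(out) + 1L]] <<- list(fixed = prefix[1],
                                       moving = prefix[l + 2],
                                       intermediates = prefix[2:(l + 1)])
      return(invisible())
    }
    for (id in remaining) recurse(c(prefix, id), setdiff(remaining, id), depth + 1)
  }
  recurse(integer(0), seq_len(n), 0)
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Median and quartiles
#'
#' @param values nonempty numeric vector.
#' @return Named vector `median`, `p25`, `p75` (linear interpolation between
#'   order statistics, quantile type 7).
#' @export
summarize_values <- function(values) {
  if (length(values) < 1) stop("values must be nonempty")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], p25 = q[2], p75 = q[3])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples are small (`<= 20`) and tie-free,
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 20 && length(b) <= 20 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  res$p.value
}

#' Linear trend of segmentation quality versus number of links
#'
#' Ordinary least-squares line through per-link-count median quality scores.
#' The intercept extrapolates to zero composed registrations, an estimate of
#' the quality attainable without any linking error.
#'
#' @param medians data frame with columns `links` and `median` (at least two
#'   distinct link counts).
#' @return List with `slope` (quality change per link), `intercept`
#'   (extrapolated zero-link quality) and the `lm` fit.
#' @export
fit_link_trend <- function(medians) {
  stopifnot(is.data.frame(medians), all(c("links", "median") %in% names(medians)))
  if (length(unique(medians$links)) < 2)
    stop("at least two distinct link counts are required")
  fit <- stats::lm(median ~ links, data = medians)
  co <- stats::coef(fit)
  list(slope = unname(co["links"]), intercept = unname(co["(Intercept)"]),
       fit = fit)
}

# warp every structure of atlas `j` onto the fixed grid through `t` with a
# single nearest-neighbor gather of the label raster
warp_structures <- function(labels_j, t, fixed_grid) {
  split_labels(warp_labels(labels_j, t, fixed_grid))
}

#' Run the leave-one-out linking experiment
#'
#' For every fixed atlas the remaining atlases are warped onto it, directly
#' and through chains of intermediate atlases, and each warped structure is
#' scored with DSC against the fixed atlas's own labels. Optionally (one
#' intermediate only, following the fused study design) the warped structures
#' of all non-fixed atlases are fused by signed-distance averaging — the
#' intermediate atlas contributing its own labels through its direct
#' registration — and the consensus is scored likewise.
#'
#' @param atlases list of atlases, each `list(image = scalar_image or NULL,
#'   labels = label_map)`, all sharing one grid.
#' @param transform_provider `function(fixed, moving)` returning a transform
#'   mapping fixed-space to moving-space coordinates for that atlas pair.
#' @param links integer vector of intermediate counts to evaluate (0 =
#'   direct; always evaluated as the matching baseline).
#' @param n_samples chains sampled per link count: a scalar, or a vector
#'   recycled along the sorted positive link counts (all chains are used
#'   when fewer exist, so a large first entry enumerates one-link chains
#'   exhaustively while longer chains stay sampled).
#' @param seed integer seed controlling chain sampling.
#' @param fuse evaluate fused segmentations for one-link chains.
#' @param k_over_s weight control ratio for fusion; 0 (default) gives equal
#'   weights. Positive values require atlas images for the similarity.
#' @param band_r band radius (mm) for structure-local similarity when
#'   `k_over_s > 0`.
#' @return A data frame of class `eval_table`: columns `fixed`, `moving`,
#'   `chain` (intermediate ids, `>`-separated), `links`, `structure`, `mode`
#'   (`direct`, `linked`, `fused_direct`, `fused_linked`), `dsc`,
#'   `dsc_direct` (matched baseline) and `rel_change` (percent).
#' @export
run_experiment <- function(atlases, transform_provider, links = 0:1,
                           n_samples = 30, seed = 1, fuse = TRUE,
                           k_over_s = 0, band_r = 10) {
  n <- length(atlases)
  if (n < 2) stop("at least 2 atlases are required")
  grid <- atlases[[1]]$labels$grid
  structures <- names(split_labels(atlases[[1]]$labels))
  rows <- list()
  push <- function(fixed, moving, chain, l, structure, mode, d, d0 = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fixed = fixed, moving = moving, chain = chain, links = l,
      structure = structure, mode = mode, dsc = d, dsc_direct = d0,
      rel_change = if (is.na(d0) || d0 == 0) NA_real_ else 100 * (d - d0) / d0,
      stringsAsFactors = FALSE)
  }

  # provider results cached per ordered pair
  tcache <- new.env(hash = TRUE, parent = emptyenv())
  get_transform <- function(i, j) {
    key <- paste0(i, "_", j)
    if (is.null(tcache[[key]])) {
      tr <- transform_provider(i, j)
      if (is.null(tr)) stop(sprintf("no transform available for pair (%d, %d)", i, j))
      tcache[[key]] <- tr
    }
    tcache[[key]]
  }

  ref_masks <- lapply(atlases, function(a) split_labels(a$labels))
  direct_dsc <- array(NA_real_, c(n, n, length(structures)),
                      dimnames = list(NULL, NULL, structures))
  direct_warp <- vector("list", n) # direct_warp[[i]][[j]] = warped masks

  # direct registrations (the l = 0 baseline)
  for (i in seq_len(n)) {
    direct_warp[[i]] <- vector("list", n)
    for (j in seq_len(n)) {
      if (j == i) next
      wm <- warp_structures(atlases[[j]]$labels, get_transform(i, j), grid)
      direct_warp[[i]][[j]] <- wm
      for (s in structures) {
        d <- suppressWarnings(dsc(wm[[s]], ref_masks[[i]][[s]]))
        direct_dsc[i, j, s] <- d
        push(i, j, "", 0L, s, "direct", d, d)
      }
    }
  }

  atlas_sims <- function(i, members, warped) {
    # per-structure similarity of each member atlas to the fixed image
    if (k_over_s == 0 || is.null(atlases[[i]]$image)) return(NULL)
    sims <- matrix(NA_real_, length(members), length(structures),
                   dimnames = list(NULL, structures))
    for (mi in seq_along(members)) {
      j <- members[mi]
      reg <- warp_image(atlases[[j]]$image, get_transform(i, j), grid)
      for (s in structures) {
        m <- warped[[mi]][[s]]
        sims[mi, s] <- if (any(m$inside))
          structure_similarity(atlases[[i]]$image, reg, m, band_r) else -1
      }
    }
    sims
  }

  fuse_and_score <- function(i, members, warped, mode, chain_str, l) {
    sims <- atlas_sims(i, members, warped)
    for (s in structures) {
      masks_s <- lapply(warped, `[[`, s)
      w <- if (is.null(sims)) NULL else fusion_weights(sims[, s], k_over_s)
      fused <- suppressWarnings(fuse_masks(masks_s, w))
      d <- suppressWarnings(dsc(fused, ref_masks[[i]][[s]]))
      d0 <- fused_direct_dsc[[i]][s]
      push(i, NA_integer_, chain_str, l, s, mode, d,
           if (mode == "fused_direct") d else d0)
    }
  }

  fused_direct_dsc <- vector("list", n)
  if (fuse) {
    for (i in seq_len(n)) {
      members <- setdiff(seq_len(n), i)
      warped <- direct_warp[[i]][members]
      sims <- atlas_sims(i, members, warped)
      vals <- numeric(length(structures))
      names(vals) <- structures
      for (s in structures) {
        masks_s <- lapply(warped, `[[`, s)
        w <- if (is.null(sims)) NULL else fusion_weights(sims[, s], k_over_s)
        fused <- suppressWarnings(fuse_masks(masks_s, w))
        vals[s] <- suppressWarnings(dsc(fused, ref_masks[[i]][[s]]))
        push(i, NA_integer_, "", 0L, s, "fused_direct", vals[s], vals[s])
      }
      fused_direct_dsc[[i]] <- vals
    }
  }

  # linked individual segmentations
  pos_links <- sort(unique(links[links > 0]))
  n_samples <- rep_len(n_samples, max(length(pos_links), 1L))
  for (li in seq_along(pos_links)) {
    l <- pos_links[li]
    cases <- sample_chains(n, l, n_samples[li], seed + l)
    for (cs in cases) {
      i <- cs$fixed; j <- cs$moving; ks <- cs$intermediates
      chain_ids <- c(ks, j)
      tlist <- vector("list", length(chain_ids))
      prev <- i
      for (ci in seq_along(chain_ids)) {
        tlist[[ci]] <- get_transform(prev, chain_ids[ci])
        prev <- chain_ids[ci]
      }
      chain <- transform_chain(tlist)
      wm <- warp_structures(atlases[[j]]$labels, chain, grid)
      chain_str <- paste(ks, collapse = ">")
      for (s in structures) {
        d <- suppressWarnings(dsc(wm[[s]], ref_masks[[i]][[s]]))
        push(i, j, chain_str, l, s, "linked", d, direct_dsc[i, j, s])
      }
    }
  }

  # fused linked segmentations (one intermediate, the fused study design)
  if (fuse && any(links >= 1) && n >= 3) {
    for (i in seq_len(n)) {
      for (k in setdiff(seq_len(n), i)) {
        members <- setdiff(seq_len(n), i)
        warped <- vector("list", length(members))
        for (mi in seq_along(members)) {
          j <- members[mi]
          if (j == k) {
            # the intermediate contributes its own labels via its direct
            # registration to the fixed image
            warped[[mi]] <- direct_warp[[i]][[k]]
          } else {
            chain <- transform_chain(get_transform(i, k), get_transform(k, j))
            warped[[mi]] <- warp_structures(atlases[[j]]$labels, chain, grid)
          }
        }
        fuse_and_score(i, members, warped, "fused_linked", as.character(k), 1L)
      }
    }
  }

  tab <- do.call(rbind, rows)
  class(tab) <- c("eval_table", "data.frame")
  tab
}

#' Aggregate an evaluation table into summary statistics
#'
#' Per structure: median relative DSC change (percent, linked vs matched
#' direct) with 25th/75th percentiles for individual and fused
#' segmentations, and the two-sided rank-sum p-value comparing linked and
#' direct DSC distributions. Per link count: pooled median DSC and the OLS
#' trend of median DSC versus links.
#'
#' @param tab an `eval_table` from [run_experiment()].
#' @return A list with elements `per_structure` (data frame), `per_links`
#'   (data frame: `links`, `median_dsc`, `p25`, `p75`, `n`), and `trend`
#'   (`slope`, `intercept`) when at least two link counts are present.
#' @export
summarize_experiment <- function(tab) {
  stopifnot(is.data.frame(tab))
  structures <- unique(tab$structure)
  per_structure <- do.call(rbind, lapply(structures, function(s) {
    sub <- tab[tab$structure == s, ]
    row <- data.frame(structure = s)
    for (mode in c("linked", "fused_linked")) {
      ml <- sub[sub$mode == mode & sub$links == 1, ]
      base_mode <- if (mode == "linked") "direct" else "fused_direct"
      mb <- sub[sub$mode == base_mode, ]
      tag <- if (mode == "linked") "individual" else "fused"
      if (nrow(ml)) {
        sm <- summarize_values(ml$rel_change[!is.na(ml$rel_change)])
        row[[paste0(tag, "_median_rel_change")]] <- sm["median"]
        row[[paste0(tag, "_p25")]] <- sm["p25"]
        row[[paste0(tag, "_p75")]] <- sm["p75"]
        row[[paste0(tag, "_p_value")]] <-
          if (nrow(mb)) rank_sum_test(ml$dsc, mb$dsc) else NA_real_
      }
    }
    row
  }))
  ind <- tab[tab$mode %in% c("direct", "linked"), ]
  per_links <- do.call(rbind, lapply(sort(unique(ind$links)), function(l) {
    v <- ind$dsc[ind$links == l]
    sm <- summarize_values(v)
    data.frame(links = l, median_dsc = sm["median"], p25 = sm["p25"],
               p75 = sm["p75"], n = length(v), row.names = NULL)
  }))
  out <- list(per_structure = per_structure, per_links = per_links)
  if (nrow(per_links) >= 2) {
    tr <- fit_link_trend(data.frame(links = per_links$links,
                                    median = per_links$median_dsc))
    out$trend <- list(slope = tr$slope, intercept = tr$intercept)
  }
  out
}
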