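#' Classify phased haplotypes over a gene region
#'
#' Collapses identical allele vectors over the region's SNPs into
#' haplotype classes, removes classes rarer than `min_count`, and reports
#' exclusions. Haplotypes with any missing allele in the region are
#' excluded (and counted in the report). Classes are named `Hap1`,
#' `Hap2`, ... by descending count, ties broken lexicographically on the
#' allele string — a deterministic order the network construction relies
#' on.
#'
#' @param panel A phased [hap_panel()].
#' @param region A [genomic_region()] (must contain at least one SNP).
#' @param min_count Minimum retained class frequency (default 2). With
#'   `unit = "haplotypes"` (default) frequency is the number of phased
#'   haplotypes; `unit = "accessions"` counts distinct carrier samples.
#' @param unit See `min_count`.
#' @return Tibble of class `haplotype_classes`: `hap_id`, `alleles`
#'   (e.g. `"0101"`), `count`, `n_carriers`, `carriers` and
#'   `carrier_haps` (list columns). Attributes: `n_excluded_missing`,
#'   `removed` (tibble of filtered classes), `region`, `sites`.
#' @export
extract_haplotypes <- function(panel, region, min_count = 2,
                               unit = c("haplotypes", "accessions")) {
  require_phased(panel, "haplotype classification")
  unit <- match.arg(unit)
  sites <- which(panel$chrom == region$chrom &
                   (panel$pos - 1) >= region$start & (panel$pos - 1) < region$end)
  if (!length(sites)) stop("region contains no SNPs", call. = FALSE)
  H <- panel$alleles[, sites, drop = FALSE]
  complete <- rowSums(is.na(H)) == 0L
  keys <- rep(NA_character_, nrow(H))
  keys[complete] <- apply(H[complete, , drop = FALSE], 1, paste, collapse = "")
  hap_sample <- rep(panel$samples, each = 2L)
  hap_idx <- rep(1:2, length(panel$samples))
  tab <- table(keys[complete])
  cls <- tibble::tibble(alleles = names(tab), count = as.integer(tab))
  cls$n_carriers <- vapply(cls$alleles, function(a) {
    length(unique(hap_sample[!is.na(keys) & keys == a]))
  }, integer(1))
  freq <- if (unit == "haplotypes") cls$count else cls$n_carriers
  keep <- freq >= min_count
  removed <- cls[!keep, c("alleles", "count", "n_carriers")]
  cls <- cls[keep, , drop = FALSE]
  cls <- cls[order(-cls$count, cls$alleles), , drop = FALSE]
  cls$hap_id <- sprintf("Hap%d", seq_len(nrow(cls)))
  cls$carriers <- lapply(cls$alleles, function(a) {
    unique(hap_sample[!is.na(keys) & keys == a])
  })
  cls$carrier_haps <- lapply(cls$alleles, function(a) {
    i <- which(!is.na(keys) & keys == a)
    tibble::tibble(sample = hap_sample[i], hap = hap_idx[i])
  })
  out <- cls[, c("hap_id", "alleles", "count", "n_carriers", "carriers", "carrier_haps")]
  attr(out, "n_excluded_missing") <- sum(!complete)
  attr(out, "removed") <- removed
  attr(out, "region") <- region
  attr(out, "sites") <- panel$pos[sites]
  class(out) <- c("haplotype_classes", class(out))
  out
}

#' Haplotype class frequencies by population group
#'
#' Per group, the percentage of its (retained-class) haplotypes falling
#' in each class. Percentages within a group sum to 100; groups carrying
#' no classified haplotype get an all-zero row and are flagged in the
#' `empty_groups` attribute.
#'
#' @param classes An [extract_haplotypes()] result.
#' @param popmap A [pop_map()] covering every carrier sample.
#' @return Long tibble: `pop`, `hap_id`, `n` (haplotypes), `pct`.
#' @export
haplotype_frequency_by_group <- function(classes, popmap) {
  long <- dplyr::bind_rows(lapply(seq_len(nrow(classes)), function(i) {
    ch <- classes$carrier_haps[[i]]
    tibble::tibble(hap_id = classes$hap_id[i], sample = ch$sample)
  }))
  missing <- setdiff(unique(long$sample), popmap$sample)
  if (length(missing)) {
    stop("sample(s) missing from the population map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  long$pop <- popmap$pop[match(long$sample, popmap$sample)]
  grid <- tidyr::expand_grid(pop = unique(popmap$pop),
                             hap_id = classes$hap_id)
  counts <- dplyr::count(long, .data$pop, .data$hap_id, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("pop", "hap_id"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::mutate(dplyr::group_by(out, .data$pop),
                       pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)
  out <- dplyr::ungroup(out)
  empty <- setdiff(unique(popmap$pop), unique(long$pop))
  attr(out, "empty_groups") <- empty
  out
}

#' Haplotype-phenotype comparison by the LSD test
#'
#' One-way ANOVA across haplotype classes followed by pairwise
#' least-significant-difference t-tests on the pooled error mean square.
#' A sample's phenotype is attributed once to every class it carries
#' (homozygotes once); `attribution = "exclusive"` restricts to samples
#' whose two haplotypes fall in the same class. Compact letters are
#' assigned greedily by descending mean: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param classes An [extract_haplotypes()] result.
#' @param phenotype Tibble/data frame with columns `sample`, `value`.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param attribution `"carrier"` (default) or `"exclusive"`.
#' @return An object of class `lsd_result`: `groups` (per-class n, mean,
#'   sd, letter), `pairs` (pairwise differences, LSD and significance),
#'   `mse`, `df`, `alpha`.
#' @export
haplotype_phenotype_lsd <- function(classes, phenotype, alpha = 0.05,
                                    attribution = c("carrier", "exclusive")) {
  attribution <- match.arg(attribution)
  ph <- stats::setNames(phenotype$value, phenotype$sample)
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(classes)), function(i) {
    carriers <- if (attribution == "carrier") {
      classes$carriers[[i]]
    } else {
      ch <- classes$carrier_haps[[i]]
      names(which(table(ch$sample) == 2L))
    }
    carriers <- carriers[carriers %in% names(ph) & !is.na(ph[carriers])]
    if (!length(carriers)) return(NULL)
    tibble::tibble(hap_id = classes$hap_id[i], sample = carriers,
                   value = unname(ph[carriers]))
  }))
  sizes <- table(rows$hap_id)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("dropping class(es) with < 2 phenotyped carriers: ",
            paste(small, collapse = ", "))
    rows <- rows[!rows$hap_id %in% small, , drop = FALSE]
  }
  if (length(unique(rows$hap_id)) < 2L) {
    stop("need >= 2 classes with >= 2 phenotyped carriers", call. = FALSE)
  }
  rows$hap_id <- factor(rows$hap_id)
  fit <- stats::aov(value ~ hap_id, data = rows)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  g <- dplyr::summarise(dplyr::group_by(rows, .data$hap_id),
                        n = dplyr::n(), mean = mean(.data$value),
                        sd = stats::sd(.data$value), .groups = "drop")
  g <- g[order(-g$mean), , drop = FALSE]
  tcrit <- stats::qt(1 - alpha / 2, df)
  ids <- as.character(g$hap_id)
  pairs <- tidyr::expand_grid(i = seq_along(ids), j = seq_along(ids))
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs$hap_a <- ids[pairs$i]; pairs$hap_b <- ids[pairs$j]
  pairs$diff <- g$mean[pairs$i] - g$mean[pairs$j]
  pairs$lsd <- tcrit * sqrt(mse * (1 / g$n[pairs$i] + 1 / g$n[pairs$j]))
  pairs$significant <- abs(pairs$diff) > pairs$lsd
  g$letter <- lsd_letters(ids, pairs)
  structure(list(groups = tibble::as_tibble(g[, c("hap_id", "n", "mean", "sd", "letter")]),
                 pairs = tibble::as_tibble(pairs[, c("hap_a", "hap_b", "diff",
                                                     "lsd", "significant")]),
                 mse = mse, df = df, alpha = alpha),
            class = "lsd_result")
}

## compact letter display, greedy insertion over means sorted descending
lsd_letters <- function(ids, pairs) {
  k <- length(ids)
  sig <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(pairs))) {
    sig[pairs$i[r], pairs$j[r]] <- sig[pairs$j[r], pairs$i[r]] <- pairs$significant[r]
  }
  groups <- list()  # each: set of indices sharing a letter
  for (i in seq_len(k)) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(sig[i, groups[[gi]]])) {
        groups[[gi]] <- c(groups[[gi]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  letters_out <- character(k)
  for (gi in seq_along(groups)) {
    for (i in groups[[gi]]) {
      letters_out[i] <- paste0(letters_out[i], letters[gi])
    }
  }
  letters_out
}

#' @export
print.lsd_result <- function(x, ...) {
  cat("LSD multiple comparison (alpha =", x$alpha,
      ", uncorrected; pooled MSE =", signif(x$mse, 4),
      "on", x$df, "df)\n")
  print(x$groups)
  invisible(x)
}

#' Median-joining haplotype network
#'
#' Builds the minimum-spanning network over haplotype classes and
#' augments it with inferred median (Steiner) vectors: majority-rule
#' medians of node triplets are added greedily while they reduce the
#' total minimum-spanning-tree length (the epsilon = 0 construction).
#' Deterministic given the class order produced by
#' [extract_haplotypes()].
#'
#' @param classes An [extract_haplotypes()] result (>= 2 classes).
#' @param epsilon Tolerance parameter; only 0 is implemented.
#' @return An object of class `haplotype_network`: `nodes` (tibble:
#'   `id`, `alleles`, `count`, `type` observed/median), `edges` (tibble:
#'   `from`, `to`, `weight` = Hamming distance), and `graph` (igraph).
#' @export
median_joining_network <- function(classes, epsilon = 0) {
  if (epsilon != 0) stop("only epsilon = 0 is implemented", call. = FALSE)
  if (nrow(classes) < 2L) stop("need >= 2 haplotype classes", call. = FALSE)
  V <- do.call(rbind, lapply(strsplit(classes$alleles, ""), as.integer))
  labels <- classes$hap_id
  counts <- classes$count
  types <- rep("observed", nrow(V))

  mst_weight <- function(M) {
    d <- as.matrix(stats::dist(M, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
    sum(igraph::E(igraph::mst(g))$weight)
  }
  repeat {
    n <- nrow(V)
    if (n < 3L) break
    W <- mst_weight(V)
    best <- NULL; best_w <- W
    combs <- utils::combn(n, 3)
    for (ci in seq_len(ncol(combs))) {
      tri <- V[combs[, ci], , drop = FALSE]
      med <- as.integer(colSums(tri) >= 2)
      if (any(apply(V, 1, function(r) all(r == med)))) next
      w <- mst_weight(rbind(V, med))
      if (w < best_w) { best_w <- w; best <- med }
    }
    if (is.null(best)) break
    V <- rbind(V, best)
    labels <- c(labels, sprintf("mv%d", sum(types == "median") + 1L))
    counts <- c(counts, 0L)
    types <- c(types, "median")
  }

  ## minimum-spanning network: process distance classes in ascending
  ## order; pairs joining distinct components at their class are edges
  d <- as.matrix(stats::dist(V, method = "manhattan"))
  n <- nrow(V)
  comp <- seq_len(n)
  edges <- list()
  for (w in sort(unique(d[upper.tri(d)]))) {
    joins <- which(upper.tri(d) & d == w, arr.ind = TRUE)
    joins <- joins[comp[joins[, 1]] != comp[joins[, 2]], , drop = FALSE]
    if (nrow(joins)) {
      edges[[length(edges) + 1L]] <-
        tibble::tibble(from = labels[joins[, 1]], to = labels[joins[, 2]],
                       weight = w)
      for (k in seq_len(nrow(joins))) {
        old <- comp[joins[k, 2]]
        comp[comp == old] <- comp[joins[k, 1]]
      }
    }
    if (length(unique(comp)) == 1L) break
  }
  edges <- dplyr::bind_rows(edges)
  nodes <- tibble::tibble(id = labels,
                          alleles = apply(V, 1, paste, collapse = ""),
                          count = counts, type = types)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Median-joining network:", sum(x$nodes$type == "observed"),
      "observed +", sum(x$nodes$type == "median"), "median nodes,",
      nrow(x$edges), "edges, total weight", sum(x$edges$weight), "\n")
  invisible(x)
}
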