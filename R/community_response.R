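#' Parse a SILVA-style lineage string
#'
#' Splits a semicolon-delimited lineage into the ranked levels
#' domain, phylum, class, order, family, genus. Missing trailing ranks are
#' returned as NA.
#'
#' @param lineage character vector of lineage strings.
#' @return character matrix, one row per lineage, columns the six ranks.
#' @export
parse_lineage <- function(lineage) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    length(p) <- length(ranks)
    p
  }, character(length(ranks))))
  colnames(out) <- ranks
  rownames(out) <- names(lineage)
  out
}

.is_unresolved <- function(x) {
  is.na(x) | grepl("^(unclassified|unknown|uncultured)?$", x,
                   ignore.case = TRUE) |
    grepl("^(unclassified|unknown)$", x, ignore.case = TRUE)
}

#' Remove non-target and singleton OTUs
#'
#' Drops OTUs whose lineage identifies them as chloroplasts, mitochondria,
#' or Archaea, OTUs not classified at the domain level, and OTUs observed
#' with a single sequence in the whole dataset (dataset-wide total count 1).
#'
#' @param counts integer matrix, samples in rows, OTUs in columns.
#' @param taxonomy named character vector mapping OTU id to lineage string;
#'   must cover every column of \code{counts}.
#' @return the filtered count matrix; attribute \code{removed} lists the
#'   dropped OTU ids by reason.
#' @export
filter_otus <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  ids <- colnames(counts)
  if (is.null(ids)) stop("count matrix must have OTU ids as column names")
  missing <- setdiff(ids, names(taxonomy))
  if (length(missing))
    stop("taxonomy missing for OTUs: ", paste(missing, collapse = ", "))
  lin <- taxonomy[ids]
  organelle <- grepl("chloroplast|mitochondri", lin, ignore.case = TRUE)
  domain <- parse_lineage(lin)[, "domain"]
  archaea <- !is.na(domain) & grepl("^archaea$", domain, ignore.case = TRUE)
  no_domain <- .is_unresolved(domain)
  singleton <- colSums(counts) == 1
  drop <- organelle | archaea | no_domain | singleton
  if (all(drop)) stop("no OTUs remain after filtering")
  out <- counts[, !drop, drop = FALSE]
  attr(out, "removed") <- list(
    organelle = ids[organelle],
    archaea = ids[archaea],
    unclassified_domain = ids[no_domain & !organelle & !archaea],
    singleton = ids[singleton & !(organelle | archaea | no_domain)])
  out
}

#' Relative abundances in percent
#'
#' @param counts matrix, samples in rows.
#' @return matrix of row percentages (each row sums to 100).
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("all-zero sample(s): ",
                          paste(rownames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 1, tot, "/") * 100
}

#' Rarefied alpha diversity
#'
#' Repeated random subsampling without replacement to a common depth, then
#' observed OTU richness and the inverse Simpson index (1/sum p_i^2) are
#' averaged over the repeats.
#'
#' @param counts integer matrix, samples in rows.
#' @param depth rarefaction depth (every sample total must reach it).
#' @param repeats number of random subsamples to average.
#' @param seed integer seed for reproducibility.
#' @return data.frame with one row per sample: \code{richness},
#'   \code{inv_simpson}, \code{depth}, \code{repeats}.
#' @export
rarefied_alpha <- function(counts, depth = 26712, repeats = 100,
                           seed = NULL) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot < depth))
    stop("samples shallower than rarefaction depth ", depth, ": ",
         paste(rownames(counts)[tot < depth], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  rich <- matrix(0, repeats, nrow(counts))
  invs <- matrix(0, repeats, nrow(counts))
  for (i in seq_len(repeats)) {
    # vegan warns heuristically when a table has no singletons; the input
    # here is validated integer counts, so that advice is muffled
    sub <- withCallingHandlers(
      vegan::rrarefy(counts, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    rich[i, ] <- rowSums(sub > 0)
    invs[i, ] <- vegan::diversity(sub, index = "invsimpson")
  }
  data.frame(sample = rownames(counts) %||% seq_len(nrow(counts)),
             richness = colMeans(rich),
             inv_simpson = colMeans(invs),
             depth = depth, repeats = repeats,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bray-Curtis dissimilarity between samples
#'
#' Rows are normalised to relative abundances and pairwise Bray-Curtis
#' dissimilarities d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) are computed.
#'
#' @param x abundance matrix, samples in rows (counts, proportions or
#'   percentages; normalised internally).
#' @return a \code{dist} object in [0, 1].
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  tot <- rowSums(x)
  if (any(tot == 0)) stop("all-zero sample(s): ",
                          paste(rownames(x)[tot == 0], collapse = ", "))
  vegan::vegdist(sweep(x, 1, tot, "/"), method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Embeds samples in \code{dims} dimensions minimising Kruskal stress-1 by
#' iterative majorisation with monotone regression, with random restarts
#' (best configuration kept). A wrapper around \code{vegan::metaMDS} on a
#' precomputed dissimilarity.
#'
#' @param d a \code{dist} or square dissimilarity matrix (>= 3 samples).
#' @param dims embedding dimensionality.
#' @param seed integer seed (controls the random restarts).
#' @param trymax maximum number of random starts.
#' @return list with \code{points} (n x dims coordinates) and \code{stress}
#'   (Kruskal stress-1, fraction).
#' @export
nmds_embed <- function(d, dims = 2, seed = NULL, trymax = 20) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) stop("NMDS needs at least 3 samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, trymax = trymax, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress, converged = fit$converged)
}

#' Cut samples into groups at a dissimilarity threshold
#'
#' Average-linkage hierarchical clustering of the dissimilarity matrix, cut
#' at the given height. Used to draw similarity hulls (e.g. 0.70 for major
#' community types, 0.32 for replicate clusters).
#'
#' @param d a \code{dist} or square dissimilarity matrix.
#' @param threshold cut height in dissimilarity units.
#' @return integer cluster labels named by sample.
#' @export
threshold_clusters <- function(d, threshold) {
  d <- stats::as.dist(d)
  stats::cutree(stats::hclust(d, method = "average"), h = threshold)
}

#' Mantel correlation between two dissimilarity matrices
#'
#' Pearson correlation of the off-diagonal entries, with a permutation p
#' value obtained by shuffling the sample labels of one matrix.
#'
#' @param d1,d2 \code{dist} objects or square matrices over the same
#'   samples.
#' @param permutations number of permutations.
#' @param seed integer seed.
#' @return list with \code{r} and \code{p}.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = NULL) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("dissimilarity matrices must cover the same samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(d1, d2, permutations = permutations)
  list(r = unname(fit$statistic), p = fit$signif)
}

#' Monte-Carlo Dirichlet centred log-ratio ensemble
#'
#' For each of \code{n_instances} Monte-Carlo instances and each sample,
#' proportions are drawn from a Dirichlet posterior with parameters
#' counts + prior, log2-transformed, and centred by subtracting the sample
#' mean log2 (clr transform in log base 2, so one unit is one duplication).
#'
#' @param counts integer matrix, samples in rows (already filtered).
#' @param n_instances number of Dirichlet Monte-Carlo instances.
#' @param prior per-taxon Dirichlet prior (pseudo-count).
#' @param seed integer seed.
#' @return object of class \code{clr_ensemble}: a list with \code{instances}
#'   (array n_instances x samples x taxa), \code{samples}, \code{taxa}.
#' @export
clr_transform <- function(counts, n_instances = 128, prior = 0.5,
                          seed = NULL) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("sample(s) with zero total count: ",
                          paste(rownames(counts)[tot == 0], collapse = ", "))
  stopifnot(n_instances >= 1, prior > 0)
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(counts); nt <- ncol(counts)
  arr <- array(NA_real_, dim = c(n_instances, ns, nt),
               dimnames = list(NULL, rownames(counts), colnames(counts)))
  shape <- counts + prior
  for (i in seq_len(n_instances)) {
    for (s in seq_len(ns)) {
      g <- stats::rgamma(nt, shape = shape[s, ], rate = 1)
      lp <- log2(g / sum(g))
      arr[i, s, ] <- lp - mean(lp)
    }
  }
  structure(list(instances = arr, samples = rownames(counts),
                 taxa = colnames(counts), n_instances = n_instances,
                 prior = prior),
            class = "clr_ensemble")
}

# Vectorised Welch t-test p-values across taxa (columns).
.welch_p <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(xb, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0 & ma == mb] <- 1
  p[se2 == 0 & ma != mb] <- 0
  p
}

# Vectorised two-sided rank-sum p-values (mid-ranks, tie-corrected normal
# approximation with continuity correction) across taxa (columns).
.ranksum_p <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb); n <- na + nb
  comb <- rbind(xa, xb)
  p <- numeric(ncol(comb))
  for (j in seq_len(ncol(comb))) {
    r <- rank(comb[, j])
    w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { p[j] <- 1; next }
    mu <- na * nb / 2
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p[j] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}

#' Between-group clr differences and effect sizes
#'
#' For every Monte-Carlo instance of a clr ensemble, computes per taxon the
#' between-group difference (mean clr of group A minus mean clr of group B,
#' log2 units), a within-group dispersion (the larger of the two
#' within-group interquartile ranges), and their ratio. Reported values are
#' medians over instances; a Welch t-test p (averaged over instances, then
#' Benjamini-Hochberg adjusted across taxa) and a rank-sum p (averaged,
#' unadjusted) accompany them.
#'
#' Taxa with zero dispersion in an instance get a signed infinite ratio for
#' that instance; a taxon whose median ratio is infinite is flagged.
#'
#' @param ens a \code{\link{clr_transform}} ensemble.
#' @param groupA,groupB character vectors of sample ids (>= 2 each).
#' @return data.frame per taxon: \code{diff} (median log2 difference),
#'   \code{dispersion}, \code{effect}, \code{p_t}, \code{p_t_bh},
#'   \code{p_w}, \code{infinite_effect}.
#' @export
effect_sizes <- function(ens, groupA, groupB) {
  stopifnot(inherits(ens, "clr_ensemble"))
  ia <- match(groupA, ens$samples)
  ib <- match(groupB, ens$samples)
  if (anyNA(ia) || anyNA(ib)) stop("group sample ids not in ensemble")
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least two samples for dispersion")
  ni <- ens$n_instances; nt <- length(ens$taxa)
  diffs <- matrix(0, ni, nt)
  disps <- matrix(0, ni, nt)
  rats <- matrix(0, ni, nt)
  pt_ <- matrix(0, ni, nt)
  pw_ <- matrix(0, ni, nt)
  for (i in seq_len(ni)) {
    xa <- ens$instances[i, ia, , drop = FALSE]
    dim(xa) <- c(length(ia), nt)
    xb <- ens$instances[i, ib, , drop = FALSE]
    dim(xb) <- c(length(ib), nt)
    d <- colMeans(xa) - colMeans(xb)
    sa <- apply(xa, 2, stats::IQR)
    sb <- apply(xb, 2, stats::IQR)
    disp <- pmax(sa, sb)
    r <- ifelse(disp > 0, d / disp, sign(d) * Inf)
    r[disp == 0 & d == 0] <- 0
    diffs[i, ] <- d; disps[i, ] <- disp; rats[i, ] <- r
    pt_[i, ] <- .welch_p(xa, xb)
    pw_[i, ] <- .ranksum_p(xa, xb)
  }
  med <- function(m) apply(m, 2, stats::median)
  p_t <- colMeans(pt_)
  out <- data.frame(taxon = ens$taxa,
                    diff = med(diffs),
                    dispersion = med(disps),
                    effect = med(rats),
                    p_t = p_t,
                    p_t_bh = stats::p.adjust(p_t, method = "BH"),
                    p_w = colMeans(pw_),
                    stringsAsFactors = FALSE)
  out$infinite_effect <- is.infinite(out$effect)
  rownames(out) <- NULL
  out
}

#' Per-taxon replicate prevalence within a sample group
#'
#' @param counts count matrix, samples in rows.
#' @param samples sample ids forming the replicate group.
#' @return named integer vector: number of replicates in which each taxon
#'   has a non-zero count.
#' @export
otu_prevalence <- function(counts, samples) {
  counts <- as.matrix(counts)
  idx <- match(samples, rownames(counts))
  if (anyNA(idx)) stop("samples not in count matrix")
  colSums(counts[idx, , drop = FALSE] > 0)
}

#' Classify rDNA responders from effect-size results
#'
#' A taxon responds to a treatment (relative to the day-0 reference) when it
#' is present in at least \code{min_prevalence} of \code{n_replicates}
#' replicate bags, its absolute effect size exceeds
#' \code{effect_threshold}, and its absolute median clr difference exceeds
#' \code{diff_threshold} log2 units (one duplication, or a decrease by
#' half).
#'
#' @param effects an \code{\link{effect_sizes}} result.
#' @param prevalence named vector from \code{\link{otu_prevalence}} for the
#'   treatment replicates.
#' @param min_prevalence minimum number of replicates with presence.
#' @param effect_threshold minimum |effect|.
#' @param diff_threshold minimum |difference| in log2 units.
#' @return the effects data.frame with added \code{prevalence},
#'   \code{responder} and \code{direction} ("up"/"down"/NA) columns.
#' @export
classify_responders_rdna <- function(effects, prevalence,
                                     min_prevalence = 2,
                                     effect_threshold = 4,
                                     diff_threshold = 1) {
  stopifnot(is.data.frame(effects), "taxon" %in% names(effects))
  prev <- prevalence[effects$taxon]
  prev[is.na(prev)] <- 0
  effects$prevalence <- as.integer(prev)
  effects$responder <- effects$prevalence >= min_prevalence &
    abs(effects$effect) > effect_threshold &
    abs(effects$diff) > diff_threshold
  effects$direction <- ifelse(effects$responder,
                              ifelse(effects$diff > 0, "up", "down"),
                              NA_character_)
  effects
}

#' Screen unreplicated (rRNA) profiles for responders
#'
#' With a single sample per condition no test statistic is possible; taxa
#' reaching at least \code{min_abundance} percent relative abundance in one
#' of the two samples are screened, and those changing at least
#' \code{fold}-fold up or down are reported. A taxon absent on day 0 that
#' reaches the abundance screen on day 23 is flagged as a new appearance and
#' counted as an increase.
#'
#' @param rel_day0,rel_day23 named numeric vectors of relative abundances in
#'   percent for the two samples (same taxa universe; missing taxa treated
#'   as 0).
#' @param min_abundance abundance screen, percent.
#' @param fold minimum fold change (decrease threshold is 1/fold).
#' @return data.frame per screened taxon: abundances, ratio, responder flag,
#'   direction, note.
#' @export
classify_responders_rrna <- function(rel_day0, rel_day23,
                                     min_abundance = 1, fold = 2) {
  taxa <- union(names(rel_day0), names(rel_day23))
  r0 <- rel_day0[taxa]; r0[is.na(r0)] <- 0
  r23 <- rel_day23[taxa]; r23[is.na(r23)] <- 0
  names(r0) <- names(r23) <- taxa
  candidate <- pmax(r0, r23) >= min_abundance
  ratio <- ifelse(r0 > 0, r23 / r0, Inf)
  new_appearance <- r0 == 0 & r23 >= min_abundance
  responder <- candidate & (ratio >= fold | ratio <= 1 / fold)
  out <- data.frame(taxon = taxa, rel_day0 = unname(r0),
                    rel_day23 = unname(r23), ratio = unname(ratio),
                    candidate = unname(candidate),
                    responder = unname(responder),
                    direction = ifelse(responder,
                                       ifelse(ratio >= fold, "up", "down"),
                                       NA_character_),
                    note = ifelse(new_appearance, "new appearance", ""),
                    stringsAsFactors = FALSE)
  out[out$candidate, , drop = FALSE]
}

#' Aggregate an OTU table to family level
#'
#' Counts are summed per family; OTUs unclassified at family rank are
#' grouped under the next-resolved higher rank, labelled
#' "unclassified <rank name>".
#'
#' @param counts count matrix, samples in rows, OTUs in columns.
#' @param taxonomy named lineage vector covering the OTUs.
#' @return count matrix, samples in rows, families in columns.
#' @export
aggregate_to_family <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  ids <- colnames(counts)
  missing <- setdiff(ids, names(taxonomy))
  if (length(missing))
    stop("taxonomy missing for OTUs: ", paste(missing, collapse = ", "))
  lin <- parse_lineage(taxonomy[ids])
  labels <- apply(lin, 1, function(rk) {
    if (!.is_unresolved(rk["family"])) return(unname(rk["family"]))
    for (upper in c("order", "class", "phylum", "domain")) {
      if (!.is_unresolved(rk[upper]))
        return(paste("unclassified", unname(rk[upper])))
    }
    "unclassified"
  })
  out <- t(rowsum(t(counts), group = labels))
  out[, order(colnames(out)), drop = FALSE]
}

# Compact letter display from a matrix of pairwise p-values: groups sharing
# a letter are not significantly different. Letters are the maximal cliques
# of the non-significance graph, ordered by group means.
.letter_display <- function(pmat, means, alpha = 0.05) {
  groups <- rownames(pmat)
  adj <- pmat >= alpha
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  ord <- order(-means)
  rank_of <- match(groups, groups[ord])
  key <- vapply(cliques, function(cl) min(rank_of[as.integer(cl)]),
                numeric(1))
  cliques <- cliques[order(key)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cliques)) {
    members <- groups[as.integer(cliques[[i]])]
    letters_out[members] <- paste0(letters_out[members], letters[i])
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Measurements are transformed (square root by default, as appropriate for
#' count- and rate-type data), a one-way ANOVA is fitted, and all-pairs
#' Tukey honest-significant-difference comparisons at level \code{alpha}
#' are summarised as a compact letter display: treatments sharing no letter
#' differ significantly.
#'
#' @param values numeric measurements.
#' @param group treatment labels (coerced to factor).
#' @param transform transformation applied before the ANOVA
#'   (default \code{sqrt}; use \code{identity} for none).
#' @param alpha significance level.
#' @return list with \code{anova} (the fitted aov), \code{tukey}
#'   (TukeyHSD table), \code{letters} (named character vector) and
#'   \code{degenerate} flag.
#' @export
anova_tukey <- function(values, group, transform = sqrt, alpha = 0.05) {
  group <- factor(group)
  if (any(grepl("-", levels(group), fixed = TRUE)))
    stop("group labels must not contain '-' (Tukey pair labels)")
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("need at least two replicates per group")
  tv <- transform(values)
  within_var <- tapply(tv, group, stats::var)
  if (all(within_var == 0, na.rm = TRUE)) {
    warning("zero within-group variance everywhere: ANOVA degenerate")
    return(list(anova = NULL, tukey = NULL,
                letters = stats::setNames(rep(NA_character_,
                                              nlevels(group)),
                                          levels(group)),
                degenerate = TRUE))
  }
  dat <- data.frame(tv = tv, group = group)
  fit <- stats::aov(tv ~ group, data = dat)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  lv <- levels(group)
  pmat <- matrix(1, nlevels(group), nlevels(group),
                 dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    pmat[a, b] <- pmat[b, a] <- tuk[k, "p adj"]
  }
  means <- tapply(tv, group, mean)
  list(anova = fit, tukey = tuk,
       letters = .letter_display(pmat, means[lv], alpha),
       degenerate = FALSE)
}
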