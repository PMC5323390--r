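#' Read an OTU count table
#'
#' Tab-separated text, first column the OTU id, remaining columns
#' per-sample integer counts (OTUs in rows, samples in columns on disk).
#' Returned transposed to the in-memory convention: samples in rows.
#'
#' @param path file path.
#' @return integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop(path, ": expected OTU id column plus samples")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop(path, ": duplicated OTU ids")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) stop(path, ": duplicated sample ids: ",
                                   paste(samples[duplicated(samples)],
                                         collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(!is.finite(m[, j]) | m[, j] < 0 |
                   m[, j] != round(m[, j]))
    if (length(bad))
      stop(path, ": non-integer or negative count at row ", bad[1] + 1,
           " (OTU ", ids[bad[1]], "), column '", samples[j], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  t(m)
}

#' Write an OTU count table
#'
#' @param counts samples x OTUs matrix.
#' @param path output file.
#' @export
write_otu_table <- function(counts, path) {
  m <- t(as.matrix(counts))
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a taxonomy map
#'
#' Two-column tab-separated text: OTU id, semicolon-delimited lineage.
#'
#' @param path file path.
#' @return named character vector (OTU id -> lineage).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop(path, ": expected columns otu_id and lineage")
  if (anyDuplicated(raw[[1]])) stop(path, ": duplicated OTU ids")
  stats::setNames(raw[[2]], raw[[1]])
}

#' Write a taxonomy map
#'
#' @param taxonomy named lineage vector.
#' @param path output file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(data.frame(otu_id = names(taxonomy),
                                lineage = unname(taxonomy),
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.measurement_columns <- list(
  cells = c("sample", "treatment", "day", "cells_per_ml"),
  oxygen = c("sample", "treatment", "o2_umol_per_l"),
  fluorescence = c("sample", "treatment", "enzyme", "time_h",
                   "fluorescence"),
  standards = c("conc_nmol_per_ml", "fluorescence"))

.measurement_nonneg <- list(
  cells = "cells_per_ml", oxygen = "o2_umol_per_l",
  fluorescence = "fluorescence", standards = "conc_nmol_per_ml")

#' Read a measurement sheet
#'
#' Tab-separated text with a header; the required columns depend on the
#' sheet type. Numeric columns are validated (finite, non-negative where
#' physically required) with errors naming the offending cell.
#'
#' @param path file path.
#' @param type one of "cells", "oxygen", "fluorescence", "standards".
#' @return data.frame.
#' @export
read_measurements <- function(path, type = c("cells", "oxygen",
                                             "fluorescence", "standards")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- .measurement_columns[[type]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  col <- .measurement_nonneg[[type]]
  v <- df[[col]]
  bad <- which(!is.finite(v) | v < 0)
  if (length(bad))
    stop(path, ": invalid value in column '", col, "', row ", bad[1] + 1)
  if ("sample" %in% names(df) && type %in% c("cells", "oxygen")) {
    key <- if (type == "cells") paste(df$sample, df$day) else df$sample
    if (anyDuplicated(key))
      stop(path, ": duplicated sample id: ",
           df$sample[duplicated(key)][1])
  }
  df
}

#' Write a measurement sheet (generic TSV writer)
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_measurements <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full incubation analysis pipeline
#'
#' Executes the analysis stages in order -- oxygen inversion, enzyme
#' kinetics, carbon budget, community statistics -- skipping any stage
#' whose inputs are absent, and returns a report bundle. All randomness
#' derives from \code{config$seed}.
#'
#' @param config a list with any of:
#'   \describe{
#'     \item{cell_counts}{data.frame (see \code{\link{read_measurements}}
#'       type "cells") or path.}
#'     \item{oxygen_readings}{data.frame (type "oxygen") or path.}
#'     \item{assays, standards}{enzyme sheets (types "fluorescence",
#'       "standards") or paths.}
#'     \item{otu_rdna, otu_rrna}{samples x OTUs matrices or paths.}
#'     \item{taxonomy}{named lineage vector or path.}
#'     \item{metadata}{sample metadata data.frame (sample, treatment, day,
#'       molecule, replicate) or path.}
#'     \item{geometry}{\code{\link{bag_geometry}} (default defaults).}
#'     \item{const}{\code{\link{budget_constants}}.}
#'     \item{control}{control treatment label (default "unfed").}
#'     \item{day0_label}{treatment label of the day-0 reference samples in
#'       the OTU metadata (default "day0").}
#'     \item{rarefaction_depth, rarefaction_repeats}{alpha-diversity
#'       settings; depth defaults to the minimum library size.}
#'     \item{n_instances, prior}{clr ensemble settings (128, 0.5).}
#'     \item{effect_threshold, diff_threshold, min_prevalence,
#'       rrna_min_abundance}{responder screen thresholds (4, 1, 2, 1).}
#'     \item{seed}{integer seed (default 1).}
#'   }
#' @return a report bundle: list with \code{oxygen}, \code{enzymes},
#'   \code{budget}, \code{community}, \code{log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  geometry <- config$geometry %||% bag_geometry()
  const <- config$const %||% budget_constants()
  control <- config$control %||% "unfed"
  day0 <- config$day0_label %||% "day0"
  seed <- config$seed %||% 1L
  get_df <- function(x, type) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1) read_measurements(x, type) else x
  }
  get_mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1) read_otu_table(x) else
      as.matrix(x)
  }
  bundle <- list(log = list(seed = seed,
                            constants = unclass(const),
                            geometry = unclass(geometry),
                            r_version = as.character(getRversion())))

  readings <- get_df(config$oxygen_readings, "oxygen")
  if (!is.null(readings)) {
    bundle$oxygen <- oxygen_uptake_table(readings, geometry,
                                         duration = const$duration,
                                         dilution_factor =
                                           const$dilution_factor)
  }

  assays <- get_df(config$assays, "fluorescence")
  standards <- get_df(config$standards, "standards")
  if (!is.null(assays) && !is.null(standards)) {
    enz <- enzyme_rate_table(assays, standards,
                             dilution_factor = const$dilution_factor)
    sm <- enz$summary
    wide <- stats::reshape(sm[, c("treatment", "enzyme", "vmax_mean")],
                           direction = "wide", idvar = "treatment",
                           timevar = "enzyme")
    names(wide) <- sub("^vmax_mean\\.", "", names(wide))
    if (all(c("chitobiase", "betaglucosidase") %in% names(wide))) {
      wide$hydrolysis_potential <- hydrolysis_potential(
        wide$chitobiase, wide$betaglucosidase, duration = const$duration)
    }
    enz$hydrolysis <- wide
    bundle$enzymes <- enz
  }

  counts <- get_df(config$cell_counts, "cells")
  if (!is.null(counts) && !is.null(bundle$oxygen)) {
    bundle$budget <- build_budget_table(counts, bundle$oxygen, const,
                                        control = control)
  }

  otu <- get_mat(config$otu_rdna)
  tax <- if (is.character(config$taxonomy) &&
               length(config$taxonomy) == 1 && is.null(names(config$taxonomy)))
    read_taxonomy(config$taxonomy) else config$taxonomy
  meta <- config$metadata
  if (is.character(meta) && length(meta) == 1)
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  if (!is.null(otu) && !is.null(tax) && !is.null(meta)) {
    if (!all(c("sample", "treatment", "day") %in% names(meta)))
      stop("metadata must have columns sample, treatment, day")
    meta_rdna <- meta[meta$sample %in% rownames(otu), ]
    filt <- filter_otus(otu, tax)
    depth <- config$rarefaction_depth %||% min(rowSums(filt))
    repeats <- config$rarefaction_repeats %||% 100L
    alpha <- rarefied_alpha(filt, depth = depth, repeats = repeats,
                            seed = seed + 1L)
    bc <- bray_curtis(filt)
    nmds <- if (nrow(filt) >= 3)
      nmds_embed(bc, seed = seed + 2L) else NULL
    ens <- clr_transform(filt, n_instances = config$n_instances %||% 128L,
                         prior = config$prior %||% 0.5, seed = seed + 3L)
    ref <- meta_rdna$sample[meta_rdna$treatment == day0]
    screens <- list()
    for (tr in setdiff(unique(meta_rdna$treatment), day0)) {
      grp <- meta_rdna$sample[meta_rdna$treatment == tr &
                                meta_rdna$day > 0]
      if (length(grp) < 2 || length(ref) < 2) next
      eff <- effect_sizes(ens, grp, ref)
      prev <- otu_prevalence(filt, grp)
      screens[[tr]] <- classify_responders_rdna(
        eff, prev,
        min_prevalence = config$min_prevalence %||% 2,
        effect_threshold = config$effect_threshold %||% 4,
        diff_threshold = config$diff_threshold %||% 1)
    }
    community <- list(filtered = filt, alpha = alpha, bray_curtis = bc,
                      nmds = nmds, rdna_screens = screens)

    rrna <- get_mat(config$otu_rrna)
    if (!is.null(rrna)) {
      meta_rrna <- meta[meta$sample %in% rownames(rrna), ]
      rel <- relative_abundance(rrna)
      ref_s <- meta_rrna$sample[meta_rrna$treatment == day0][1]
      rrna_screens <- list()
      for (tr in setdiff(unique(meta_rrna$treatment), day0)) {
        s <- meta_rrna$sample[meta_rrna$treatment == tr &
                                meta_rrna$day > 0][1]
        if (is.na(s) || is.na(ref_s)) next
        rrna_screens[[tr]] <- classify_responders_rrna(
          rel[ref_s, ], rel[s, ],
          min_abundance = config$rrna_min_abundance %||% 1)
      }
      community$rrna_screens <- rrna_screens
    }
    bundle$community <- community
  }
  bundle
}
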