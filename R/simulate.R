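#' Configuration for the synthetic multi-omic generator
#'
#' Describes a CCLE-like cohort: several continuous layers with
#' heavy-tailed (log-normal) feature distributions, one boolean
#' genomic-alteration layer, an 11-feature pathway-activity layer, a
#' skewed tissue composition, and an ActArea drug response driven by a
#' latent sensitivity score. A configurable number of "marker" features
#' per layer is coupled to that score, so every downstream stage can be
#' validated against known ground truth.
#'
#' Signal redundancy across layers is controlled by `redundancy`: each
#' layer's contribution is a convex mix of a shared latent and a
#' layer-private latent (re-scaled to unit variance), so `redundancy = 1`
#' makes all marker layers carry exactly the same signal (the redundant
#' regime seen in real multi-omic cohorts) and `redundancy = 0` makes
#' them complementary.
#'
#' @param n_samples Number of cell lines.
#' @param layers `data.frame` with columns `name`, `modality`
#'   (`continuous`/`boolean`), `n_features`. A layer named `"pathways"`
#'   must have exactly 11 features.
#' @param n_tissues Number of tissue-of-origin groups; drawn multinomially
#'   with a geometrically decaying distribution (a few large groups, many
#'   small ones).
#' @param markers_per_layer Named integer vector: planted markers per layer.
#' @param effect_size Named numeric vector: marker shift in units of the
#'   feature's own standard deviation (log scale for continuous layers,
#'   logit scale for boolean layers).
#' @param redundancy Fraction in \[0, 1\] of marker signal shared across
#'   layers through the common latent score.
#' @param noise_sd Standard deviation of the noise added to ActArea.
#' @param drugs Character vector of drug names; planted markers drive the
#'   first drug, additional drugs get independent latent scores.
#' @param include_tissue_layer Add a one-hot categorical layer encoding
#'   tissue of origin (default `TRUE`).
#' @param marker_ids Optional named list (layer -> feature ids) pinning
#'   the planted marker identities, e.g. to generate an external cohort
#'   carrying the same markers as a training cohort under a different
#'   seed; default: markers drawn at random per layer.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   dataset.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_samples = 300,
                       layers = default_sim_layers(),
                       n_tissues = 12,
                       markers_per_layer = c(transcriptomics = 5, proteomics = 3, genomics = 3),
                       effect_size = c(transcriptomics = 1, proteomics = 1, genomics = 1),
                       redundancy = 0.7,
                       noise_sd = 0.5,
                       drugs = "DRUG1",
                       include_tissue_layer = TRUE,
                       marker_ids = NULL,
                       seed = 1) {
  layers <- as.data.frame(layers, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "modality", "n_features") %in% names(layers)))
  if (n_samples <= 0 || n_tissues <= 0 || any(layers$n_features <= 0))
    stop("all counts must be positive")
  if (any(effect_size < 0)) stop("effect sizes must be >= 0")
  if (redundancy < 0 || redundancy > 1) stop("redundancy must be in [0, 1]")
  if (!all(layers$modality %in% c("continuous", "boolean")))
    stop("generator layer modality must be continuous or boolean")
  if (anyDuplicated(layers$name)) stop("duplicated layer names")
  unknown <- setdiff(names(markers_per_layer), layers$name)
  if (length(unknown)) stop("markers_per_layer names unknown: ", paste(unknown, collapse = ", "))
  for (nm in names(markers_per_layer)) {
    if (markers_per_layer[[nm]] > layers$n_features[layers$name == nm])
      stop("markers_per_layer for '", nm, "' exceeds its n_features")
  }
  if ("pathways" %in% layers$name && layers$n_features[layers$name == "pathways"] != 11)
    stop("the pathway-activity layer has exactly 11 features")
  if (!is.null(marker_ids)) {
    bad <- setdiff(names(marker_ids), layers$name)
    if (length(bad)) stop("marker_ids names unknown: ", paste(bad, collapse = ", "))
  }
  structure(list(n_samples = n_samples, layers = layers, n_tissues = n_tissues,
                 markers_per_layer = markers_per_layer, effect_size = effect_size,
                 redundancy = redundancy, noise_sd = noise_sd, drugs = drugs,
                 include_tissue_layer = include_tissue_layer,
                 marker_ids = marker_ids, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default layer table for the synthetic generator
#'
#' Desk-scale analogue of the CCLE layer structure: transcriptomics (2000
#' transcripts), miRNA (300), proteomics/RPPA (200), metabolomics (150),
#' 11 pathway activities, and a boolean genomic-alteration table (300).
#'
#' @return A `data.frame` with columns `name`, `modality`, `n_features`.
#' @export
default_sim_layers <- function() {
  data.frame(
    name = c("transcriptomics", "mirna", "proteomics", "metabolomics", "pathways", "genomics"),
    modality = c("continuous", "continuous", "continuous", "continuous", "continuous", "boolean"),
    n_features = c(2000, 300, 200, 150, 11, 300),
    stringsAsFactors = FALSE
  )
}

# Tissue name pool; extended with synthetic names when n_tissues is larger.
tissue_pool <- c("BREAST", "LUNG", "SKIN", "OVARY", "LARGE_INTESTINE",
                 "HAEMATOPOIETIC_AND_LYMPHOID_TISSUE", "PANCREAS",
                 "CENTRAL_NERVOUS_SYSTEM", "LIVER", "STOMACH", "KIDNEY",
                 "BONE", "OESOPHAGUS", "URINARY_TRACT", "PLEURA")

#' Generate a synthetic multi-omic dataset with known ground truth
#'
#' Continuous features are log-normal with per-feature log-scale drawn
#' from a gamma prior (heavy-tailed, RPKM-like); boolean features are
#' Bernoulli. Planted marker features are shifted (continuous, log scale)
#' or flipped (boolean, logit scale) in proportion to the layer's latent
#' contribution. ActArea is an affine function of the latent sensitivity
#' score plus Gaussian noise, so the tercile labels downstream are
#' recoverable from the markers.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a `multiomic_dataset`) and
#'   `truth` (a `ground_truth`: `marker_ids` per layer, per-sample
#'   `latent_score`, per-layer `contributions`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples

  pool <- tissue_pool
  if (config$n_tissues > length(pool))
    pool <- c(pool, sprintf("TISSUE%02d", seq_len(config$n_tissues - length(pool))))
  tnames <- pool[seq_len(config$n_tissues)]
  tprob <- 0.65 ^ (seq_len(config$n_tissues) - 1)
  tissue <- sample(tnames, n, replace = TRUE, prob = tprob / sum(tprob))
  ids <- sprintf("CL%04d_%s", seq_len(n), tissue)

  z <- rnorm(n)  # shared latent
  r <- config$redundancy
  mix <- function(u) {
    s <- r * z + (1 - r) * u
    denom <- sqrt(r^2 + (1 - r)^2)
    s / denom
  }

  layers <- list()
  marker_ids <- list()
  contributions <- list()
  for (i in seq_len(nrow(config$layers))) {
    nm <- config$layers$name[i]
    p <- config$layers$n_features[i]
    modality <- config$layers$modality[i]
    fids <- sprintf("%s_f%04d", nm, seq_len(p))
    m <- if (nm %in% names(config$markers_per_layer)) config$markers_per_layer[[nm]] else 0L
    eff <- if (nm %in% names(config$effect_size)) config$effect_size[[nm]] else 0
    s_l <- mix(rnorm(n))
    midx <- if (!is.null(config$marker_ids[[nm]])) {
      pin <- match(config$marker_ids[[nm]], fids)
      if (anyNA(pin)) stop("pinned marker ids not among layer '", nm, "' features")
      sort(pin)
    } else if (m > 0) sort(sample.int(p, m)) else integer(0)

    if (modality == "continuous") {
      mu <- rnorm(p, mean = 1, sd = 0.5)
      # moderate dispersion heterogeneity: marker effects (not baseline
      # spread) should dominate the variance ranking, as for real markers
      sdlog <- rgamma(p, shape = 16, rate = 16) + 0.1
      e <- matrix(rnorm(n * p), n, p)
      if (length(midx)) e[, midx] <- e[, midx] + eff * s_l
      vals <- exp(sweep(sweep(e, 2, sdlog, "*"), 2, mu, "+"))
    } else {
      base_p <- rbeta(p, 2, 5)
      eta <- matrix(qlogis(base_p), n, p, byrow = TRUE)
      if (length(midx)) eta[, midx] <- eta[, midx] + eff * s_l
      vals <- matrix(rbinom(n * p, 1, plogis(eta)), n, p)
    }
    dimnames(vals) <- list(ids, fids)
    layers[[nm]] <- omic_layer(nm, vals, modality = modality)
    if (length(midx) > 0 && eff > 0) {
      marker_ids[[nm]] <- fids[midx]
      contributions[[nm]] <- s_l
    }
  }

  if (config$include_tissue_layer) {
    th <- outer(tissue, tnames, `==`) * 1
    dimnames(th) <- list(ids, tnames)
    layers[["tissue"]] <- omic_layer("tissue", th, modality = "categorical")
  }

  latent <- if (length(contributions)) {
    as.numeric(scale(Reduce(`+`, contributions) / length(contributions)))
  } else z
  names(latent) <- ids

  response <- do.call(rbind, lapply(seq_along(config$drugs), function(d) {
    lat_d <- if (d == 1) latent else rnorm(n)
    data.frame(sample_id = ids, drug = config$drugs[d],
               act_area = 3 + lat_d + rnorm(n, sd = config$noise_sd),
               stringsAsFactors = FALSE)
  }))

  dataset <- multiomic_dataset(layers, response, tissue = setNames(tissue, ids))
  truth <- structure(list(marker_ids = marker_ids, latent_score = latent,
                          contributions = contributions, config = config),
                     class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Write a synthetic dataset as a CCLE-style fixture directory
#'
#' Continuous layers are written as GCT v1.2, boolean and categorical
#' layers as 0/1 CSV tables, the response as a wide CSV (one ActArea
#' column per drug), plus a `manifest.json` describing the files and an
#' optional `truth.json` sidecar with the planted ground truth. The
#' directory round-trips through [read_fixture()].
#'
#' @param dataset A `multiomic_dataset`.
#' @param directory Output directory (created if needed).
#' @param truth Optional `ground_truth` to serialize alongside.
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(dataset, directory, truth = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(layers = list(), response = "response.csv")
  for (l in dataset$layers) {
    if (l$modality == "continuous") {
      fn <- paste0(l$name, ".gct")
      write_gct(l, file.path(directory, fn))
    } else {
      fn <- paste0(l$name, ".csv")
      df <- data.frame(sample_id = rownames(l$values), l$values,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write.csv(df, file.path(directory, fn), row.names = FALSE, quote = FALSE)
    }
    manifest$layers[[l$name]] <- list(file = fn, modality = l$modality)
  }
  wide <- data.frame(sample_id = dataset$sample_ids, stringsAsFactors = FALSE)
  for (d in unique(dataset$response$drug)) {
    sub <- dataset$response[dataset$response$drug == d, ]
    wide[[d]] <- sub$act_area[match(wide$sample_id, sub$sample_id)]
  }
  write.csv(wide, file.path(directory, "response.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(marker_ids = truth$marker_ids,
           latent_score = as.list(truth$latent_score),
           contributions = lapply(truth$contributions, as.numeric)),
      file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(directory)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Fixture directory containing `manifest.json`.
#' @return A `multiomic_dataset`.
#' @export
read_fixture <- function(directory) {
  mf <- jsonlite::read_json(file.path(directory, "manifest.json"))
  layers <- lapply(names(mf$layers), function(nm) {
    entry <- mf$layers[[nm]]
    path <- file.path(directory, entry$file)
    switch(entry$modality,
           continuous = read_gct(path, name = nm),
           boolean = read_boolean_table(path, name = nm),
           categorical = {
             l <- read_boolean_table(path, name = nm)
             l$modality <- "categorical"
             l
           })
  })
  names(layers) <- names(mf$layers)
  wide <- read.csv(file.path(directory, mf$response), check.names = FALSE,
                   stringsAsFactors = FALSE)
  drugs <- setdiff(names(wide), "sample_id")
  response <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(sample_id = wide$sample_id, drug = d, act_area = wide[[d]],
               stringsAsFactors = FALSE)
  }))
  multiomic_dataset(layers, response)
}
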