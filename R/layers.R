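#' Construct a single omic layer
#'
#' An omic layer is one named feature matrix, oriented samples x features,
#' with a modality tag describing the measurement type: `"continuous"`
#' (RPKM/FPKM-like expression, RPPA, metabolite abundances, pathway
#' activities), `"boolean"` (presence/absence of genomic alterations) or
#' `"categorical"` (one-hot encoded factors such as tissue of origin).
#'
#' @param name Layer name, e.g. `"transcriptomics"`.
#' @param values Numeric matrix, samples in rows (unique rownames = sample
#'   ids), features in columns (unique colnames = feature ids).
#' @param modality One of `"continuous"`, `"boolean"`, `"categorical"`.
#' @return An object of class `omic_layer`.
#' @export
omic_layer <- function(name, values, modality = c("continuous", "boolean", "categorical")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("layer '", name, "': values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("layer '", name, "': values must carry sample rownames and feature colnames")
  if (anyDuplicated(rownames(values)))
    stop("layer '", name, "': duplicated sample ids")
  if (anyDuplicated(colnames(values)))
    stop("layer '", name, "': duplicated feature ids")
  if (modality %in% c("boolean", "categorical")) {
    v <- values[!is.na(values)]
    if (!all(v %in% c(0, 1)))
      stop("layer '", name, "': ", modality, " values must be 0/1")
  }
  structure(list(name = name, modality = modality, values = values),
            class = "omic_layer")
}

#' @export
print.omic_layer <- function(x, ...) {
  cat(sprintf("<omic_layer> %s [%s]: %d samples x %d features\n",
              x$name, x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sample identifiers of an object
#' @param x An `omic_layer` or `multiomic_dataset`.
#' @return Character vector of sample ids, in storage order.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.omic_layer <- function(x) rownames(x$values)

#' @export
sample_ids.multiomic_dataset <- function(x) x$sample_ids

#' Feature identifiers of a layer
#' @param layer An `omic_layer`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(layer) colnames(layer$values)

#' Assemble a sample-aligned multi-omic dataset
#'
#' Layers are restricted to the samples present in every layer (and in the
#' response table, if given), in the order of the first layer. Tissue of
#' origin is taken from `tissue` or, when `NULL`, parsed from the sample
#' names via [extract_tissue()].
#'
#' @param layers Named list of [omic_layer()] objects (names default to the
#'   layers' own names).
#' @param response Long-format drug response `data.frame` with columns
#'   `sample_id`, `drug`, `act_area` (ActArea: normalized area over the
#'   dose-response curve; larger = more sensitive).
#' @param tissue Optional named character vector of tissue per sample.
#' @return An object of class `multiomic_dataset` with elements `layers`,
#'   `sample_ids`, `tissue`, `response`.
#' @export
multiomic_dataset <- function(layers, response, tissue = NULL) {
  if (length(layers) == 0) stop("at least one layer required")
  if (is.null(names(layers)) || any(names(layers) == ""))
    names(layers) <- vapply(layers, function(l) l$name, character(1))
  for (l in layers) if (!inherits(l, "omic_layer")) stop("layers must be omic_layer objects")
  req <- c("sample_id", "drug", "act_area")
  if (!is.data.frame(response) || !all(req %in% names(response)))
    stop("response must be a data.frame with columns sample_id, drug, act_area")
  response$sample_id <- as.character(response$sample_id)
  response$drug <- as.character(response$drug)

  common <- Reduce(intersect, lapply(layers, sample_ids))
  common <- intersect(common, unique(response$sample_id))
  if (length(common) == 0) stop("no samples shared by all layers and the response table")
  ord <- sample_ids(layers[[1]])
  common <- ord[ord %in% common]
  layers <- lapply(layers, function(l) {
    l$values <- l$values[common, , drop = FALSE]
    l
  })
  if (is.null(tissue)) {
    tissue <- extract_tissue(common)
  } else {
    if (is.null(names(tissue))) stop("tissue must be named by sample id")
    missing <- setdiff(common, names(tissue))
    if (length(missing)) stop("tissue undefined for samples: ", paste(head(missing), collapse = ", "))
    tissue <- tissue[common]
  }
  response <- response[response$sample_id %in% common, , drop = FALSE]
  structure(list(layers = layers, sample_ids = common,
                 tissue = tissue, response = response),
            class = "multiomic_dataset")
}

#' @export
print.multiomic_dataset <- function(x, ...) {
  cat(sprintf("<multiomic_dataset> %d samples, %d tissues, %d drugs\n",
              length(x$sample_ids), length(unique(x$tissue)),
              length(unique(x$response$drug))))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Names of the layers in a dataset
#' @param dataset A `multiomic_dataset`.
#' @return Character vector.
#' @export
layer_names <- function(dataset) names(dataset$layers)

#' Numeric design matrix for one layer
#'
#' Returns the layer's values restricted to `samples` (all samples by
#' default), ready to be fed to a first-level learner. Boolean and one-hot
#' categorical layers are already numeric 0/1.
#'
#' @param dataset A `multiomic_dataset`.
#' @param layer Layer name.
#' @param samples Optional character vector of sample ids.
#' @return Numeric matrix samples x features.
#' @export
layer_matrix <- function(dataset, layer, samples = NULL) {
  if (!layer %in% names(dataset$layers)) stop("unknown layer: ", layer)
  v <- dataset$layers[[layer]]$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing)) stop("samples absent from layer '", layer, "': ",
                              paste(head(missing), collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  v
}

# Restrict every layer, the tissue vector and the response table to `ids`
# (used after sample drops; keeps all layers aligned).
subset_samples <- function(dataset, ids) {
  dataset$layers <- lapply(dataset$layers, function(l) {
    l$values <- l$values[ids, , drop = FALSE]
    l
  })
  dataset$sample_ids <- ids
  dataset$tissue <- dataset$tissue[ids]
  dataset$response <- dataset$response[dataset$response$sample_id %in% ids, , drop = FALSE]
  dataset
}
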