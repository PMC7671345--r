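MODEL_FORMAT_VERSION <- "hlapanel-model-1"

#' Save a set of trained locus models to a versioned JSON archive
#'
#' The archive is a self-describing JSON tree embedding a format version and
#' the run configuration used for training; frequencies are written at full
#' double precision so a load reproduces the model bit for bit.
#'
#' @param models An `hla_model_set` (named list of `locus_model`s).
#' @param path Output file.
#' @param cfg The [run_config()] used for training (stored in the archive).
#' @return `path`, invisibly.
#' @export
save_hla_model <- function(models, path, cfg = NULL) {
  stopifnot(is.list(models), length(models) >= 1)
  # doubles go out as %.17g strings: 17 significant digits round-trip IEEE
  # doubles exactly, which plain JSON numbers (15-16 digits) do not
  ser_cl <- function(cl) {
    list(snps = cl$snps,
         pattern = cl$table$pattern,
         hla = cl$table$hla,
         freq = sprintf("%.17g", cl$table$freq),
         oob_acc = sprintf("%.17g", cl$oob_acc))
  }
  ser_model <- function(m) {
    list(locus = m$locus,
         alleles = m$alleles,
         n_train = m$n_train,
         snp_pool = m$snp_pool,
         calibration = if (!is.null(m$calibration))
           list(x = sprintf("%.17g", m$calibration$x),
                y = sprintf("%.17g", m$calibration$y)),
         classifiers = lapply(m$classifiers, ser_cl))
  }
  tree <- list(format_version = MODEL_FORMAT_VERSION,
               run_config = if (!is.null(cfg)) unclass(cfg),
               models = lapply(models, ser_model))
  jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a set of locus models saved by [save_hla_model()]
#'
#' Refuses archives whose format version does not match the current one —
#' no silent best-effort load.
#'
#' @param path Archive file.
#' @return An `hla_model_set`; the stored run configuration, if any, is
#'   attached as attribute `run_config`.
#' @export
load_hla_model <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tree <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (is.null(tree$format_version) ||
      !identical(tree$format_version, MODEL_FORMAT_VERSION))
    stop("model archive version mismatch: found ",
         tree$format_version %||% "<none>", ", expected ",
         MODEL_FORMAT_VERSION)
  de_cl <- function(cl) {
    list(snps = as.character(cl$snps),
         table = data.frame(pattern = as.character(cl$pattern),
                            hla = as.character(cl$hla),
                            freq = as.numeric(unlist(cl$freq)),
                            stringsAsFactors = FALSE),
         oob_acc = as.numeric(unlist(cl$oob_acc)))
  }
  de_model <- function(m) {
    structure(list(locus = as.character(m$locus),
                   classifiers = lapply(m$classifiers, de_cl),
                   alleles = as.character(m$alleles),
                   n_train = as.integer(m$n_train),
                   snp_pool = as.character(m$snp_pool),
                   calibration = if (!is.null(m$calibration))
                     list(x = as.numeric(unlist(m$calibration$x)),
                          y = as.numeric(unlist(m$calibration$y)))),
              class = "locus_model")
  }
  models <- lapply(tree$models, de_model)
  names(models) <- vapply(models, `[[`, "", "locus")
  class(models) <- "hla_model_set"
  if (!is.null(tree$run_config))
    attr(models, "run_config") <- tree$run_config
  models
}

#' Write imputation calls to TSV
#'
#' @param calls Calls data.frame (`sample`, `locus`, `allele1`, `allele2`,
#'   `posterior`, `flagged`, `batch`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read imputation calls from TSV
#'
#' @param path Calls TSV written by [write_calls()].
#' @return Calls data.frame.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "locus", "allele1", "allele2", "posterior")
  if (!all(need %in% names(tab)))
    stop("calls TSV must have columns ", paste(need, collapse = ", "))
  if (is.null(tab$flagged)) tab$flagged <- FALSE
  if (is.null(tab$batch)) tab$batch <- NA_integer_
  tab
}
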