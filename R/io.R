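# Plain-text containers. Datasets are directories of CSV (features matrix,
# phenotype table with empty cell = missing) plus JSON metadata recording
# the edge-order convention; models are JSON with base64-encoded IEEE-754
# doubles so a save/load round trip reproduces predictions bit-identically.

fmt_num <- function(x) {
  s <- sprintf("%.17g", x)
  s[!is.finite(x) & !is.na(x)] <- as.character(x[!is.finite(x) & !is.na(x)])
  s[is.na(x)] <- ""
  s
}

parse_num <- function(s) {
  v <- rep(NA_real_, length(s))
  ok <- !is.na(s) & nzchar(s)
  v[ok] <- as.numeric(s[ok])
  v
}

#' Write a dataset to a plain-text container directory
#'
#' Writes `features.csv` (participant_id plus one column per edge, full
#' 17-significant-digit precision), `phenotypes.csv` (participant_id plus
#' one column per phenotype, empty cell = missing) and `meta.json` (name,
#' size class, train/validation split, parcel count, edge-order convention).
#'
#' @param dataset A [source_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "source_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(dataset$features)
  fdf <- data.frame(participant_id = ids,
                    apply(dataset$features, 2, fmt_num),
                    check.names = FALSE)
  colnames(fdf) <- c("participant_id",
                     sprintf("edge_%05d", seq_len(ncol(dataset$features))))
  utils::write.csv(fdf, file.path(dir, "features.csv"), row.names = FALSE,
                   quote = FALSE)
  pdf <- data.frame(participant_id = ids,
                    apply(dataset$phenotypes, 2, fmt_num),
                    check.names = FALSE)
  colnames(pdf) <- c("participant_id", colnames(dataset$phenotypes))
  utils::write.csv(pdf, file.path(dir, "phenotypes.csv"), row.names = FALSE,
                   quote = FALSE)
  p <- as.integer(round((1 + sqrt(1 + 8 * ncol(dataset$features))) / 2))
  meta <- list(
    format = "metamatchr-dataset", version = 1L,
    name = dataset$name, size_class = dataset$size_class,
    n_parcels = p,
    edge_order = "strict lower triangle, row-major over rows i > j",
    split = as.list(stats::setNames(dataset$split, ids)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a dataset container written by [write_dataset()]
#'
#' Phenotype rows are aligned to feature rows by participant id; any
#' mismatch is reported with counts.
#'
#' @param dir Container directory.
#' @return A [source_dataset()].
#' @export
read_dataset <- function(dir) {
  for (f in c("features.csv", "phenotypes.csv", "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("malformed dataset container: missing ", f, " in ", dir, call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (!identical(meta$format, "metamatchr-dataset")) {
    stop("not a metamatchr dataset container: ", dir, call. = FALSE)
  }
  fdf <- utils::read.csv(file.path(dir, "features.csv"),
                         colClasses = "character", check.names = FALSE)
  pdf <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                         colClasses = "character", check.names = FALSE)
  fid <- fdf$participant_id; pid <- pdf$participant_id
  if (!setequal(fid, pid) || anyDuplicated(fid) || anyDuplicated(pid)) {
    stop("participant id mismatch between features and phenotypes: ",
         length(setdiff(fid, pid)), " only in features, ",
         length(setdiff(pid, fid)), " only in phenotypes, ",
         sum(duplicated(fid)) + sum(duplicated(pid)), " duplicated",
         call. = FALSE)
  }
  pdf <- pdf[match(fid, pid), , drop = FALSE]
  x <- vapply(fdf[-1], parse_num, numeric(nrow(fdf)))
  if (nrow(fdf) == 1) x <- matrix(x, nrow = 1)
  rownames(x) <- fid
  colnames(x) <- NULL
  y <- vapply(pdf[-1], parse_num, numeric(nrow(pdf)))
  if (nrow(pdf) == 1) y <- matrix(y, nrow = 1)
  rownames(y) <- fid
  colnames(y) <- colnames(pdf)[-1]
  split <- unlist(meta$split)[fid]
  source_dataset(meta$name, x, y, size_class = meta$size_class,
                 split = unname(split))
}

# --- recursive model (de)serialization ---------------------------------------

encode_node <- function(x) {
  if (is.null(x)) return(list(.t = "null"))
  if (is.double(x)) {
    return(list(.t = "dbl", dim = dim(x), dimnames = dimnames(x),
                nms = names(x),
                b64 = jsonlite::base64_enc(writeBin(as.double(x), raw()))))
  }
  if (is.integer(x) || is.logical(x) || is.character(x)) {
    return(list(.t = "atm", mode = mode(x), v = as.vector(x), dim = dim(x),
                nms = names(x)))
  }
  if (is.data.frame(x)) {
    return(list(.t = "df", cls = class(x),
                cols = lapply(stats::setNames(as.list(x), names(x)), encode_node)))
  }
  if (is.list(x)) {
    return(list(.t = "lst", cls = class(x), nms = names(x),
                items = lapply(unclass(x), encode_node)))
  }
  stop("cannot serialize component of type ", typeof(x), call. = FALSE)
}

decode_node <- function(n) {
  switch(n$.t,
    null = NULL,
    dbl = {
      raw <- jsonlite::base64_dec(n$b64)
      v <- readBin(raw, "double", n = length(raw) / 8)
      if (!is.null(n$dim)) {
        dim(v) <- unlist(n$dim)
        if (!is.null(n$dimnames)) {
          dimnames(v) <- lapply(n$dimnames, function(d) if (is.null(d)) NULL else unlist(d))
        }
      } else if (!is.null(n$nms)) {
        names(v) <- unlist(n$nms)
      }
      v
    },
    atm = {
      v <- unlist(n$v)
      if (is.null(v)) v <- vector(n$mode, 0)
      storage.mode(v) <- n$mode
      if (!is.null(n$dim)) dim(v) <- unlist(n$dim)
      else if (!is.null(n$nms)) names(v) <- unlist(n$nms)
      v
    },
    df = {
      cols <- lapply(n$cols, decode_node)
      tibble::as_tibble(cols)
    },
    lst = {
      items <- lapply(n$items, decode_node)
      if (!is.null(n$nms)) names(items) <- unlist(n$nms)
      cls <- unlist(n$cls)
      if (!identical(cls, "list")) class(items) <- cls
      items
    },
    stop("unknown serialized node type: ", n$.t, call. = FALSE)
  )
}

#' Save / load a trained model as JSON
#'
#' All model objects in the package (ridge, KRR, network, stacking,
#' multilayer, adapted) are plain data and serialize to a JSON file whose
#' numeric payloads are base64-encoded doubles: a round trip reproduces
#' predictions bit-identically. The file carries a format/version field;
#' a mismatch is an explicit error.
#'
#' @param model A model object.
#' @param path Output file.
#' @return `path` ([save_model()]) / the model ([load_model()]), invisibly
#'   resp. visibly.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "metamatchr-model", version = 1L,
              type = class(model)[1], payload = encode_node(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "metamatchr-model")) {
    stop(path, " is not a metamatchr model file", call. = FALSE)
  }
  if (!identical(as.integer(obj$version), 1L)) {
    stop("model file version ", obj$version, " is not supported (expected 1)",
         call. = FALSE)
  }
  decode_node(obj$payload)
}
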