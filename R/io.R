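#' Read a response/response-time dataset from CSV
#'
#' Two layouts are supported. `"long"`: one row per observed person-item
#' pair, header `person_id,item_id,response,time_seconds`; pairs absent from
#' the file are masked unobserved. `"wide"`: a pair of CSV matrices (first
#' responses, then times in seconds), each with person ids in the first
#' column and item ids as the remaining header fields; empty cells are
#' masked. Person and item order is first-appearance order; ids are kept as
#' strings.
#'
#' @param path file path (long) or length-2 character vector of paths
#'   (wide: responses file, times file).
#' @param format "long" or "wide".
#' @return A `sathm_data` object.
#' @export
read_dataset <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") read_long(path) else read_wide(path)
}

read_long <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(person_id = "character",
                                             item_id = "character"))
  need <- c("person_id", "item_id", "response", "time_seconds")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$person_id, df$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate (person, item) pair: (%s, %s)", d$person_id, d$item_id))
  }
  bad <- which(!(df$response %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("row %d: response must be 0 or 1 (got %s)", bad[1], df$response[bad[1]]))
  bad <- which(!is.finite(df$time_seconds) | df$time_seconds <= 0)
  if (length(bad))
    stop(sprintf("row %d: time_seconds must be > 0 (got %s)", bad[1], df$time_seconds[bad[1]]))
  pid <- unique(df$person_id); iid <- unique(df$item_id)
  N <- length(pid); J <- length(iid)
  U <- matrix(NA_integer_, N, J); Tm <- matrix(NA_real_, N, J)
  ii <- match(df$person_id, pid); jj <- match(df$item_id, iid)
  U[cbind(ii, jj)] <- as.integer(df$response)
  Tm[cbind(ii, jj)] <- df$time_seconds
  mask <- !is.na(U)
  U[!mask] <- 0L; Tm[!mask] <- 1
  new_sathm_data(U, Tm, mask, person_ids = pid, item_ids = iid)
}

read_wide <- function(path) {
  if (length(path) != 2)
    stop("wide format needs two paths: responses CSV then times CSV")
  for (p in path) if (!file.exists(p)) stop("file not found: ", p)
  rd <- function(p) {
    df <- utils::read.csv(p, check.names = FALSE, colClasses = "character")
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    list(ids = ids, items = colnames(df)[-1], m = m)
  }
  Ru <- rd(path[1]); Rt <- rd(path[2])
  if (!identical(Ru$ids, Rt$ids) || !identical(Ru$items, Rt$items))
    stop("responses and times matrices must share person ids and item ids")
  mask <- !is.na(Ru$m) & !is.na(Rt$m)
  if (any(Ru$m[mask] != 0 & Ru$m[mask] != 1)) stop("responses must be 0/1")
  if (any(Rt$m[mask] <= 0)) stop("times must be > 0")
  U <- Ru$m; U[!mask] <- 0; Tm <- Rt$m; Tm[!mask] <- 1
  storage.mode(U) <- "integer"
  dimnames(U) <- dimnames(Tm) <- dimnames(mask) <- NULL
  new_sathm_data(U, Tm, mask, person_ids = Ru$ids, item_ids = Ru$items)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]. Long format writes only observed cells, in
#' person-major then item order, with at least 15 significant digits;
#' wide format writes the two matrices with empty strings for unobserved
#' cells.
#'
#' @param dataset a `sathm_data`.
#' @param path file path (long) or length-2 vector (wide).
#' @param format "long" or "wide".
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "sathm_data"))
  fmt <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  if (format == "long") {
    ord <- which(dataset$mask, arr.ind = TRUE)
    ord <- ord[order(ord[, 1], ord[, 2]), , drop = FALSE]
    df <- data.frame(person_id = dataset$person_ids[ord[, 1]],
                     item_id = dataset$item_ids[ord[, 2]],
                     response = dataset$responses[ord],
                     time_seconds = fmt(dataset$times[ord]))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (length(path) != 2) stop("wide format needs two paths")
    wr <- function(m, p, digits = FALSE) {
      mm <- matrix("", nrow(m), ncol(m))
      mm[dataset$mask] <- if (digits) fmt(m[dataset$mask]) else m[dataset$mask]
      df <- data.frame(person_id = dataset$person_ids, mm, check.names = FALSE)
      colnames(df) <- c("person_id", dataset$item_ids)
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    }
    wr(dataset$responses, path[1])
    wr(dataset$times, path[2], digits = TRUE)
  }
  invisible(path)
}

#' Write generating values ("truth") to a JSON sidecar
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  x <- list(item = as.list(truth$item), zeta = truth$zeta,
            person = as.list(truth$person),
            sigma_theta_tau = truth$sigma_theta_tau,
            design = list(n_persons = truth$design$n_persons,
                          n_items = truth$design$n_items,
                          sigma_theta_tau = truth$design$sigma_theta_tau,
                          item_mean = truth$design$item_mean,
                          item_cov = as.vector(truth$design$item_cov),
                          generating_model = truth$design$generating_model,
                          seed = truth$design$seed))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read generating values from a JSON sidecar
#'
#' @param path a file written by [write_truth()].
#' @return A `sim_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- sim_design(n_persons = x$design$n_persons,
                       n_items = x$design$n_items,
                       sigma_theta_tau = x$design$sigma_theta_tau,
                       item_mean = x$design$item_mean,
                       item_cov = matrix(x$design$item_cov, 2, 2),
                       generating_model = x$design$generating_model,
                       seed = x$design$seed)
  structure(list(item = as.data.frame(x$item), zeta = x$zeta,
                 person = as.data.frame(x$person),
                 sigma_theta_tau = x$sigma_theta_tau, design = design),
            class = "sim_truth")
}

#' Read an MCMC configuration from a YAML or JSON file
#'
#' The file holds any subset of the [mcmc_config()] fields (`n_iter`,
#' `burn_in`, `n_chains`, `thin`, `seed`, `alpha_truncated`, `adapt_batch`,
#' `vague_var`); unspecified fields take the defaults passed in `...`.
#' Format is chosen by extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path configuration file path.
#' @param ... default field values overridden by the file (see
#'   [mcmc_config()]).
#' @return An `mcmc_config`.
#' @export
read_mcmc_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  base <- list(...)
  allowed <- names(formals(mcmc_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  args <- utils::modifyList(base[names(base) %in% allowed], as.list(vals))
  do.call(mcmc_config, args)
}

#' Write posterior chains to per-parameter CSV files
#'
#' One CSV per chain (`chain1.csv`, `chain2.csv`, ...) with a column per
#' parameter and a row per retained draw.
#'
#' @param fit a `sathm_fit`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_chains <- function(fit, dir) {
  stopifnot(inherits(fit, "sathm_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in seq_along(fit$draws))
    utils::write.csv(as.data.frame(fit$draws[[ch]]),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  invisible(dir)
}
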