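#' Load and validate a run configuration
#'
#' JSON run configurations drive the command-line front end and batch
#' scripting. Schema (unknown keys are rejected):
#' \preformatted{
#' {
#'   "architecture": "simple_repression" | "simple_activation" |
#'                   "dual_repression" | "dual_activation" | "looping" |
#'                   {explicit architecture JSON},
#'   "params": { kinetic_params overrides },
#'   "task": "moments" | "distribution" | "simulate" | "scan" | "study",
#'   "task_options": { task-specific options },
#'   "seed": integer (required for simulate/study),
#'   "out": output path prefix
#' }
#' }
#' Parameter defaults are filled from [promnoise_defaults()]; every random
#' task must carry an explicit seed.
#'
#' @param path path to a JSON configuration file.
#' @return A validated `run_config` object (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(obj)
}

validate_config <- function(obj) {
  allowed <- c("architecture", "params", "task", "task_options", "seed",
               "out")
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  tasks <- c("moments", "distribution", "simulate", "scan", "study")
  if (is.null(obj$task) || !obj$task %in% tasks)
    stop("config 'task' must be one of: ", paste(tasks, collapse = ", "),
         call. = FALSE)
  builders <- c("simple_repression", "simple_activation", "dual_repression",
                "dual_activation", "looping")
  if (is.null(obj$architecture))
    stop("config must name an 'architecture'", call. = FALSE)
  if (is.character(obj$architecture) &&
      !obj$architecture %in% builders)
    stop("unknown architecture '", obj$architecture, "'; expected one of: ",
         paste(builders, collapse = ", "), call. = FALSE)
  pdefaults <- promnoise_defaults()
  attr(pdefaults, "sources") <- NULL
  over <- obj$params
  if (!is.null(over)) {
    bad <- setdiff(names(over), names(pdefaults))
    if (length(bad))
      stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    neg <- names(over)[vapply(over, function(v) !is.numeric(v) || v < 0,
                              logical(1))]
    if (length(neg))
      stop("kinetic parameter(s) must be nonnegative numbers: ",
           paste(neg, collapse = ", "), call. = FALSE)
  }
  params <- do.call(kinetic_params,
                    modifyList(unclass(pdefaults), as.list(over %||% list())))
  if (obj$task %in% c("simulate", "study") &&
      (is.null(obj$seed) || !is.finite(as.numeric(obj$seed))))
    stop("task '", obj$task, "' requires an explicit integer 'seed'",
         call. = FALSE)
  structure(list(architecture = obj$architecture, params = params,
                 task = obj$task,
                 task_options = as.list(obj$task_options %||% list()),
                 seed = if (!is.null(obj$seed)) as.integer(obj$seed),
                 out = obj$out),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config a `run_config` object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(architecture = config$architecture,
              params = unclass(config$params),
              task = config$task)
  if (length(config$task_options)) obj$task_options <- config$task_options
  if (!is.null(config$seed)) obj$seed <- config$seed
  if (!is.null(config$out)) obj$out <- config$out
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resolve a configured architecture to a `promoter_architecture`
#'
#' @param config a `run_config`.
#' @return A [promoter_architecture()].
#' @export
config_architecture <- function(config) {
  stopifnot(inherits(config, "run_config"))
  a <- config$architecture
  if (is.character(a)) {
    switch(a,
           simple_repression = simple_repression(config$params),
           simple_activation = simple_activation(config$params),
           dual_repression = dual_repression(config$params),
           dual_activation = dual_activation(config$params),
           looping = looping_repression(config$params))
  } else {
    promoter_architecture(states = as.character(a$states),
                          transitions = a$transitions,
                          transcription_rates =
                            as.numeric(a$transcription_rates),
                          name = a$name %||% "config")
  }
}

#' Random valid architecture fixtures
#'
#' Deterministic (per seed) generator of random irreducible promoter
#' architectures for property-style testing: a random cycle through all
#' states guarantees strong connectivity, extra random edges add
#' structure, rates are log-uniform over 4 decades around 0.05 s^-1 and
#' transcription rates log-uniform around 0.33 s^-1 with a fraction of
#' silent states.
#'
#' @param n_states number of promoter states, 1..8.
#' @param seed integer seed.
#' @param p_extra probability of each extra directed edge.
#' @param p_silent probability that a state is transcriptionally silent.
#' @return A [promoter_architecture()].
#' @export
fixture_random_architecture <- function(n_states, seed, p_extra = 0.3,
                                        p_silent = 0.25) {
  stopifnot(n_states >= 1, n_states <= 8)
  set.seed(as.integer(seed))
  states <- paste0("s", seq_len(n_states))
  lograte <- function(n, center) center * 10^runif(n, -2, 2)
  if (n_states == 1L) {
    return(promoter_architecture(states, NULL, lograte(1, 0.33),
                                 name = sprintf("fixture_seed%d", seed)))
  }
  ord <- sample(n_states)
  from <- states[ord]
  to <- states[c(ord[-1], ord[1])]
  for (i in seq_len(n_states)) for (j in seq_len(n_states)) {
    if (i != j && runif(1) < p_extra &&
        !(states[i] %in% from[to == states[j]])) {
      from <- c(from, states[i]); to <- c(to, states[j])
    }
  }
  rates <- lograte(length(from), 0.05)
  r <- lograte(n_states, 0.33)
  r[runif(n_states) < p_silent] <- 0
  if (all(r == 0)) r[sample(n_states, 1)] <- lograte(1, 0.33)
  promoter_architecture(states,
                        transitions_df(from, to, rates), r,
                        name = sprintf("fixture_seed%d", seed))
}

# fixed 12-significant-digit float formatting for bit-stable outputs
fmt12 <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

#' Write results with stable formatting
#'
#' Writes a data frame (or an object with an `as.data.frame` method, such
#' as a `moment_result`) as TSV, CSV or JSON. Floats are formatted with
#' 12 significant digits so identical inputs give byte-identical files;
#' tabular formats carry a provenance comment line with the package
#' version, a content hash of the data and the seed when given.
#'
#' @param x object to write.
#' @param path output file path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param seed optional seed recorded in the provenance line.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "csv", "json"),
                          seed = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  dfc <- as.data.frame(lapply(df, fmt12), stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (format == "json") {
    jsonlite::write_json(dfc, path, auto_unbox = FALSE)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  hash <- content_hash(dfc)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# promnoise %s hash=%s%s",
                     as.character(utils::packageVersion("promnoise")), hash,
                     if (!is.null(seed)) sprintf(" seed=%d",
                                                 as.integer(seed)) else ""),
             con)
  utils::write.table(dfc, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# small deterministic content hash (djb2 over the serialized text)
content_hash <- function(df) {
  txt <- paste(c(names(df), unlist(df, use.names = FALSE)), collapse = "\x1f")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' Write a distribution's marginal (and joint) as TSV
#'
#' @param dist a [steady_state_distribution()].
#' @param path output file for the two-column marginal (`m`, `probability`).
#' @param joint_path optional output for the wide joint table (one column
#'   per promoter state).
#' @return `path`, invisibly.
#' @export
write_distribution_tsv <- function(dist, path, joint_path = NULL) {
  stopifnot(inherits(dist, "steady_state_distribution"))
  df <- data.frame(m = seq_along(dist$marginal) - 1L,
                   probability = dist$marginal)
  write_results(df, path, "tsv")
  if (!is.null(joint_path)) {
    jd <- as.data.frame(dist$joint)
    names(jd) <- dist$states
    jd <- cbind(m = seq_along(dist$marginal) - 1L, jd)
    write_results(jd, joint_path, "tsv")
  }
  invisible(path)
}

#' Serialize a moment result as a flat TSV row
#'
#' One row: architecture name, parameter hash, species, mean, variance,
#' fano, cv2, promoter_noise.
#'
#' @param mom a `moment_result`.
#' @param path output file.
#' @param architecture architecture name recorded in the row.
#' @param params optional [kinetic_params()] hashed into the row.
#' @return `path`, invisibly.
#' @export
write_moments_tsv <- function(mom, path, architecture = "", params = NULL) {
  stopifnot(inherits(mom, "moment_result"))
  phash <- if (is.null(params)) "" else
    content_hash(as.data.frame(unclass(params)))
  df <- cbind(data.frame(architecture = architecture, params_hash = phash,
                         stringsAsFactors = FALSE),
              as.data.frame(mom))
  df$second_moment <- NULL
  write_results(df, path, "tsv")
}
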