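#' Read / write a count series with covariates
#'
#' Plain-text comma-delimited tables with header `t,x[,z1..zq]`. Counts
#' must be non-negative integers; malformed rows are reported by row
#' number. The intercept is implicit on disk and added automatically when
#' the series enters a fit.
#'
#' @param path File path.
#' @return `read_series()` returns a tibble ordered by `t`;
#'   `write_series()` returns `path` invisibly.
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("t", "x") %in% names(df))) {
    abort("file must have columns `t` and `x`.")
  }
  bad <- which(is.na(df$x) | df$x < 0 | df$x != floor(df$x))
  if (length(bad)) {
    abort(sprintf("non-count value in column `x` at data row %d.", bad[1]))
  }
  df <- df[order(df$t), , drop = FALSE]
  as_tibble(df)
}

#' @rdname read_series
#' @param data Series tibble (columns `t`, `x`, covariates).
#' @export
write_series <- function(data, path) {
  if (!all(c("t", "x") %in% names(data))) {
    abort("`data` must have columns `t` and `x`.")
  }
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin argv-driven wrapper over the package's functions, used by the
#' `inst/cli/tvmttinar` script. Subcommands:
#' \describe{
#'   \item{simulate}{`--model <design> --n <int> --seed <int> --out <csv>`}
#'   \item{fit}{`--in <csv> --method cls|cml --r <int>|grid --R 0|1`}
#'   \item{test}{`--in <csv> --stat T1|T2|T3 --r <int> --R 0|1 [--level a]`}
#'   \item{study}{`--name <design> --task test|estimate|threshold
#'     --stat T1|T2|T3 --method cls|cml --n <int> --reps <int> --seed <int>`}
#' }
#' Results go to stdout (or `--out`); the resolved configuration is logged
#' to stderr.
#'
#' @param args Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tvmttinar <simulate|fit|test|study> [--flag value ...]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  log_msg <- function(...) message("[tvmttinar ", utils::packageVersion("tvmttinar"),
                                   "] ", ...)
  out <- tryCatch({
    switch(cmd,
      simulate = {
        need(opts, c("model", "n", "out"))
        if (!is.null(opts$seed)) set.seed(as.integer(opts$seed))
        log_msg("simulate model=", opts$model, " n=", opts$n,
                " seed=", opts$seed %||% "none")
        d <- simulate_design(opts$model, as.integer(opts$n))
        write_series(d, opts$out)
        log_msg("wrote ", nrow(d), " rows to ", opts$out)
        0L
      },
      fit = {
        need(opts, c("in", "method"))
        d <- read_series(opts[["in"]])
        R <- as.integer(opts$R %||% 0)
        method <- match.arg(opts$method, c("cls", "cml"))
        rflag <- opts$r %||% "grid"
        log_msg("fit method=", method, " r=", rflag, " R=", R)
        fit <- if (identical(rflag, "grid")) {
          fit_threshold(d, R, method)
        } else if (method == "cls") {
          fit_cls(d, as.integer(rflag), R)
        } else {
          fit_cml(d, as.integer(rflag), R)
        }
        emit_table(tidy(fit), opts$out)
        print(glance(fit))
        0L
      },
      test = {
        need(opts, c("in", "stat", "r"))
        d <- read_series(opts[["in"]])
        R <- as.integer(opts$R %||% 0)
        r <- as.integer(opts$r)
        level <- as.numeric(opts$level %||% 0.05)
        log_msg("test stat=", opts$stat, " r=", r, " R=", R)
        res <- switch(match.arg(opts$stat, c("T1", "T2", "T3")),
          T1 = test_piecewise(fit_cls(d, r, R), level),
          T2 = test_covariates_wald(fit_cls(d, r, R), level),
          T3 = test_covariates_lr(d, r, R, level))
        print(res)
        emit_table(tidy(res), opts$out)
        0L
      },
      study = {
        need(opts, c("name", "n", "reps"))
        seed <- if (is.null(opts$seed)) NULL else as.integer(opts$seed)
        n <- as.integer(opts$n); reps <- as.integer(opts$reps)
        task <- opts$task %||% "test"
        log_msg("study name=", opts$name, " task=", task, " n=", n,
                " reps=", reps, " seed=", opts$seed %||% "none")
        res <- switch(task,
          test = mc_test(opts$name, n, reps, stat = opts$stat %||% "T1",
                         level = as.numeric(opts$level %||% 0.05),
                         seed = seed),
          estimate = mc_estimation(opts$name, n, reps,
                                   method = opts$method %||% "cml",
                                   r_known = is.null(opts$grid),
                                   seed = seed),
          threshold = mc_threshold(opts$name, n, reps,
                                   method = opts$method %||% "cml",
                                   seed = seed),
          abort("unknown --task; use test, estimate or threshold."))
        emit_table(res, opts$out)
        0L
      },
      { message("unknown subcommand '", cmd, "'\n", usage); 1L }
    )
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(out)
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort(sprintf("unexpected argument '%s'.", a))
    key <- substring(a, 3)
    if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}

need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss)) {
    abort(sprintf("missing required flag(s): %s",
                  paste0("--", miss, collapse = ", ")))
  }
}

emit_table <- function(tbl, out = NULL) {
  if (is.null(out)) {
    utils::write.csv(tbl, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(tbl, out, row.names = FALSE, quote = FALSE)
  }
  invisible(tbl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
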