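#' Construct a binned recording session
#'
#' A binned session holds the population firing-rate matrix of one contiguous
#' recording (time bins by units) together with the time-aligned kinematics
#' (here 2-D hand velocity), the bin width and free-form metadata. It is the
#' raw material of every decoder in the package.
#'
#' @param rates Numeric matrix, `n_bins x C`, nonnegative firing rates
#'   (spikes/s, or counts per bin -- record the unit in `metadata` if it
#'   matters downstream).
#' @param kinematics Numeric matrix, `n_bins x D`, kinematic targets. The
#'   conventional layout is `D = 2` velocity components `vx`, `vy` (a.u./s).
#' @param bin_width Positive scalar, bin width in seconds. Default 0.064
#'   (64 ms bins).
#' @param session_id Character scalar naming the session.
#' @param metadata Named list of additional scalars (e.g. the generator
#'   configuration for synthetic sessions).
#'
#' @return An object of class `binned_session`: a list with elements `rates`,
#'   `kinematics`, `bin_width`, `session_id`, `metadata`.
#' @seealso [assemble_sequences()], [split_session()], [read_session()],
#'   [make_session()]
#' @export
binned_session <- function(rates, kinematics, bin_width = 0.064,
                           session_id = "session", metadata = list()) {
  rates <- as.matrix(rates)
  kinematics <- as.matrix(kinematics)
  if (!is.numeric(rates) || !is.numeric(kinematics)) {
    stop("`rates` and `kinematics` must be numeric matrices", call. = FALSE)
  }
  if (anyNA(rates) || anyNA(kinematics)) {
    stop("session arrays must not contain missing values", call. = FALSE)
  }
  if (nrow(rates) != nrow(kinematics)) {
    stop(sprintf(
      "`rates` (%d rows) and `kinematics` (%d rows) must cover the same bins",
      nrow(rates), nrow(kinematics)
    ), call. = FALSE)
  }
  if (ncol(rates) < 1L) stop("need at least one unit (C >= 1)", call. = FALSE)
  if (any(rates < 0)) stop("firing rates must be nonnegative", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a positive scalar (seconds)", call. = FALSE)
  }
  structure(
    list(
      rates = unname(rates),
      kinematics = unname(kinematics),
      bin_width = as.numeric(bin_width),
      session_id = as.character(session_id),
      metadata = metadata
    ),
    class = "binned_session"
  )
}

#' @export
print.binned_session <- function(x, ...) {
  cat(sprintf(
    "<binned_session> '%s': %d bins x %d units, D=%d, bin width %g s\n",
    x$session_id, nrow(x$rates), ncol(x$rates), ncol(x$kinematics), x$bin_width
  ))
  invisible(x)
}

#' Number of bins / units of a session
#' @param session A [binned_session()].
#' @return Integer scalar.
#' @export
n_bins <- function(session) nrow(session$rates)

#' @rdname n_bins
#' @export
n_units <- function(session) ncol(session$rates)

#' Write a session to CSV
#'
#' The on-disk format is a plain CSV with a header row (`u1..uC`, `vx`, `vy`,
#' ...) preceded by `#key value` comment lines carrying `bin_width_s`,
#' `session_id` and any scalar metadata. Values are written with 17
#' significant digits so that a write/read round trip reproduces the arrays
#' bit for bit.
#'
#' @param session A [binned_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "binned_session"))
  C <- ncol(session$rates)
  D <- ncol(session$kinematics)
  kin_names <- if (D == 2L) c("vx", "vy") else paste0("k", seq_len(D))
  header <- c(
    sprintf("#bin_width_s %.17g", session$bin_width),
    sprintf("#session_id %s", session$session_id)
  )
  for (key in names(session$metadata)) {
    val <- session$metadata[[key]]
    if (length(val) == 1L && (is.numeric(val) || is.character(val))) {
      header <- c(header, sprintf(
        "#%s %s", key,
        if (is.numeric(val)) sprintf("%.17g", val) else as.character(val)
      ))
    }
  }
  mat <- cbind(session$rates, session$kinematics)
  body <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  lines <- c(
    header,
    paste(c(paste0("u", seq_len(C)), kin_names), collapse = ","),
    body
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a session from disk
#'
#' Reads the CSV session format written by [write_session()]: rate columns
#' prefixed `u`, kinematic columns (`vx`, `vy`, or `k*`), and `#key value`
#' metadata lines. The arrays are validated against the `binned_session`
#' invariants (equal row counts, nonnegative rates, no missing values).
#'
#' @param path File path. Only `.csv` sessions are supported.
#' @return A [binned_session()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    stop("HDF5 sessions are not supported; use the CSV session format",
         call. = FALSE)
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  data_lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(data_lines) < 2L) {
    stop("malformed session file: no data rows", call. = FALSE)
  }
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#(\\S+)\\s+(.*)$", ml))[[1]]
    if (length(m) == 3L) {
      meta[[m[2]]] <- utils::type.convert(m[3], as.is = TRUE)
    }
  }
  df <- utils::read.csv(text = paste(data_lines, collapse = "\n"),
                        check.names = FALSE)
  rate_cols <- grep("^u[0-9]+$", names(df))
  kin_cols <- setdiff(seq_along(df), rate_cols)
  if (length(rate_cols) == 0L || length(kin_cols) == 0L) {
    stop("session file must contain rate columns (u1..uC) and kinematic columns",
         call. = FALSE)
  }
  bin_width <- meta[["bin_width_s"]]
  session_id <- meta[["session_id"]]
  if (is.null(bin_width)) {
    stop("session file is missing the bin_width_s metadata line", call. = FALSE)
  }
  meta[["bin_width_s"]] <- NULL
  meta[["session_id"]] <- NULL
  binned_session(
    rates = as.matrix(df[rate_cols]),
    kinematics = as.matrix(df[kin_cols]),
    bin_width = bin_width,
    session_id = if (is.null(session_id)) "session" else session_id,
    metadata = meta
  )
}

#' @rdname read_session
#' @param format Either `"csv"` (the native format) -- kept as an argument so
#'   callers can be explicit.
#' @export
load_session <- function(path, format = c("csv")) {
  format <- match.arg(format)
  read_session(path)
}

#' Assemble sliding-window decoder inputs
#'
#' Cuts a session into all full-length input windows. Window `k` covers
#' session bins `k .. k + T - 1` (inclusive, 1-based) and is paired with the
#' kinematic target at its most recent bin, the clock index `t = k + T - 1`.
#' Timesteps are ordered with `tau = 1` the oldest and `tau = T` the most
#' recent bin of the window. The first `T - 1` bins of the session produce no
#' sample: causal decoding requires a full history window, and padding would
#' fabricate neural activity.
#'
#' @param session A [binned_session()].
#' @param T_len Window length in bins (the decoder's number of timesteps, T).
#' @return An object of class `sequence_dataset`: list with `x` (array
#'   `n_samples x T x C`), `y` (matrix `n_samples x D`), `clock_index`
#'   (integer vector, bin index of each sample's most recent timestep),
#'   `T_len`, `bin_width`.
#' @export
assemble_sequences <- function(session, T_len) {
  stopifnot(inherits(session, "binned_session"))
  T_len <- as.integer(T_len)
  if (length(T_len) != 1L || is.na(T_len) || T_len < 1L) {
    stop("`T_len` must be a positive integer", call. = FALSE)
  }
  nb <- n_bins(session)
  if (T_len > nb) {
    stop(sprintf("window length T=%d exceeds the session length (%d bins)",
                 T_len, nb), call. = FALSE)
  }
  C <- n_units(session)
  ns <- nb - T_len + 1L
  x <- array(0, dim = c(ns, T_len, C))
  for (tau in seq_len(T_len)) {
    x[, tau, ] <- session$rates[tau:(tau + ns - 1L), , drop = FALSE]
  }
  structure(
    list(
      x = x,
      y = session$kinematics[T_len:nb, , drop = FALSE],
      clock_index = T_len:nb,
      T_len = T_len,
      bin_width = session$bin_width
    ),
    class = "sequence_dataset"
  )
}

#' @export
print.sequence_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<sequence_dataset> %d samples, T=%d, C=%d, D=%d\n",
              d[1], d[2], d[3], ncol(x$y)))
  invisible(x)
}

#' Number of samples in a sequence dataset
#' @param dataset A `sequence_dataset`.
#' @return Integer scalar.
#' @export
n_samples <- function(dataset) dim(dataset$x)[1]

#' Specify a train/test split
#'
#' Two policies are supported. `"prefix"` reproduces the single-session
#' protocol in which the first `train_end` bins form the training set and the
#' remainder the test set. `"kfold"` partitions the session into `n_folds`
#' contiguous folds whose sizes differ by at most one bin.
#'
#' @param train_end Integer bin index: last bin of the training prefix
#'   (required for the prefix policy).
#' @param policy `"prefix"` or `"kfold"`.
#' @param n_folds Number of folds for the kfold policy (default 10).
#' @param val_fraction Optional fraction of the training prefix to reserve as
#'   a validation tail (0 disables; consumed by [run_tts()]).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_end = NULL, policy = c("prefix", "kfold"),
                       n_folds = 10L, val_fraction = 0) {
  policy <- match.arg(policy)
  if (policy == "prefix") {
    if (is.null(train_end)) {
      stop("prefix policy requires `train_end`", call. = FALSE)
    }
    train_end <- as.integer(train_end)
  }
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(train_end = train_end, policy = policy,
         n_folds = as.integer(n_folds), val_fraction = val_fraction),
    class = "split_spec"
  )
}

subset_session <- function(session, idx, suffix) {
  binned_session(
    rates = session$rates[idx, , drop = FALSE],
    kinematics = session$kinematics[idx, , drop = FALSE],
    bin_width = session$bin_width,
    session_id = paste0(session$session_id, suffix),
    metadata = session$metadata
  )
}

#' Split a session for training and testing
#'
#' @param session A [binned_session()].
#' @param spec A [split_spec()]. With the prefix policy the result is
#'   `list(train =, test =)` where `train` holds bins `1..train_end` and
#'   `test` the remaining suffix; their union reconstructs the session. With
#'   the kfold policy the result is `list(folds =)`, a list of `n_folds`
#'   contiguous bin-index vectors whose sizes differ by at most 1.
#' @return See Details above.
#' @export
split_session <- function(session, spec) {
  stopifnot(inherits(session, "binned_session"), inherits(spec, "split_spec"))
  nb <- n_bins(session)
  if (spec$policy == "prefix") {
    te <- spec$train_end
    if (is.na(te) || te <= 0L || te >= nb) {
      stop(sprintf("`train_end` must lie strictly inside the session (1 < %d < %d)",
                   te, nb), call. = FALSE)
    }
    list(
      train = subset_session(session, seq_len(te), "/train"),
      test = subset_session(session, (te + 1L):nb, "/test")
    )
  } else {
    k <- spec$n_folds
    if (k < 2L || k > nb) stop("`n_folds` out of range", call. = FALSE)
    sizes <- rep(nb %/% k, k)
    extra <- nb %% k
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    list(folds = Map(function(s, e) s:e, starts, ends))
  }
}
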