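#' Entropy ledger for a rigid-residue scan
#'
#' Bookkeeping container for scan-level statistics.  Each row is one run,
#' keyed by (state, rigid_residue) where \code{rigid_residue = 0} denotes the
#' unperturbed run.  A run carries its whole-system entropy S and optionally
#' the per-residue entropy vector.
#'
#' @param states character vector of admissible state labels.
#' @return An empty \code{EntropyLedger}.
#' @export
entropy_ledger <- function(states = c("unbound", "bound")) {
  structure(list(table = data.frame(state = character(), rigid_residue = integer(),
                                    S = numeric(), n_frames = integer(),
                                    stringsAsFactors = FALSE),
                 per_residue = list(), states = states),
            class = "EntropyLedger")
}

ledger_key <- function(state, rigid_residue) paste0(state, ":", rigid_residue)

#' Add one run to an entropy ledger
#'
#' @param ledger an \code{EntropyLedger}.
#' @param state state label.
#' @param rigid_residue residue held rigid in the run (0 = unperturbed).
#' @param S whole-system configurational entropy, kcal/(mol K).
#' @param per_residue optional numeric vector of per-residue entropies.
#' @param n_frames frames analyzed.
#' @return The updated ledger.  Exactly one row per (state, rigid_residue) is
#'   allowed.
#' @export
add_run <- function(ledger, state, rigid_residue, S, per_residue = NULL,
                    n_frames = NA_integer_) {
  stopifnot(inherits(ledger, "EntropyLedger"))
  if (!state %in% ledger$states)
    stop("unknown state '", state, "' (expected: ",
         paste(ledger$states, collapse = ", "), ")")
  rigid_residue <- as.integer(rigid_residue)
  key <- ledger_key(state, rigid_residue)
  if (key %in% ledger_key(ledger$table$state, ledger$table$rigid_residue))
    stop("duplicate run: ", key)
  ledger$table <- rbind(ledger$table,
                        data.frame(state = state, rigid_residue = rigid_residue,
                                   S = S, n_frames = as.integer(n_frames),
                                   stringsAsFactors = FALSE))
  if (!is.null(per_residue)) ledger$per_residue[[key]] <- as.numeric(per_residue)
  ledger
}

#' @export
print.EntropyLedger <- function(x, ...) {
  cat("EntropyLedger:", nrow(x$table), "runs over states {",
      paste(x$states, collapse = ", "), "}\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

ledger_lookup <- function(ledger, state, rigid_residue) {
  i <- which(ledger$table$state == state & ledger$table$rigid_residue == rigid_residue)
  if (!length(i)) NULL else ledger$table$S[i]
}

#' Relative entropies of a scan
#'
#' \eqn{\Delta S(run) = S(run) - S(reference)} for every run of a state.  The
#' default reference is the state's own unperturbed run; with
#' \code{reference = "unbound"} the unperturbed unbound run is used for both
#' states (the alternative reading of the scan convention).
#'
#' @param ledger an \code{EntropyLedger}.
#' @param state which state's runs to difference.
#' @param reference \code{"own"} (default) or \code{"unbound"}.
#' @return Data frame with \code{rigid_residue}, \code{S}, \code{delta_S},
#'   sorted by residue.
#' @export
delta_entropy <- function(ledger, state, reference = c("own", "unbound")) {
  stopifnot(inherits(ledger, "EntropyLedger"))
  reference <- match.arg(reference)
  ref_state <- if (reference == "own") state else "unbound"
  s_ref <- ledger_lookup(ledger, ref_state, 0L)
  if (is.null(s_ref))
    stop("missing unperturbed reference row for state '", ref_state, "'")
  tab <- ledger$table[ledger$table$state == state, , drop = FALSE]
  tab <- tab[order(tab$rigid_residue), ]
  data.frame(rigid_residue = tab$rigid_residue, S = tab$S,
             delta_S = tab$S - s_ref)
}

#' Bound-minus-unbound entropy differences
#'
#' \eqn{\Delta\Delta S(r) = S_{bound}(r) - S_{unbound}(r)} for every rigid
#' residue r present in both states, including r = 0 (the unperturbed pair).
#'
#' @param ledger an \code{EntropyLedger} with both states populated.
#' @return Data frame with \code{rigid_residue}, \code{S_unbound},
#'   \code{S_bound}, \code{dd_S}; unmatched residues are skipped with a
#'   warning.
#' @export
delta_delta_entropy <- function(ledger) {
  stopifnot(inherits(ledger, "EntropyLedger"))
  tu <- ledger$table[ledger$table$state == "unbound", ]
  tb <- ledger$table[ledger$table$state == "bound", ]
  common <- intersect(tu$rigid_residue, tb$rigid_residue)
  extra <- setdiff(union(tu$rigid_residue, tb$rigid_residue), common)
  if (length(extra))
    warning("skipping unmatched rigid-residue rows: ",
            paste(sort(extra), collapse = ", "))
  common <- sort(common)
  su <- tu$S[match(common, tu$rigid_residue)]
  sb <- tb$S[match(common, tb$rigid_residue)]
  data.frame(rigid_residue = common, S_unbound = su, S_bound = sb,
             dd_S = sb - su)
}

#' Screen for key residues
#'
#' Residues whose rigid-residue \eqn{|\Delta\Delta S|} is strictly smaller
#' than the unperturbed-pair reference value: holding such a residue rigid
#' erases (part of) the entropic signature of binding, marking it as a
#' candidate allosteric residue.
#'
#' @param dds a data frame from \code{\link{delta_delta_entropy}}.
#' @param reference_dds reference \eqn{|\Delta\Delta S|}; default the r = 0
#'   row of \code{dds}.
#' @return Data frame of passing residues sorted ascending by
#'   \code{abs_dd_S}; the boundary case (equality) is excluded.
#' @export
key_residue_screen <- function(dds, reference_dds = NULL) {
  if (is.null(reference_dds)) {
    i0 <- which(dds$rigid_residue == 0L)
    if (!length(i0)) stop("no unperturbed (rigid_residue = 0) row and no explicit reference")
    reference_dds <- abs(dds$dd_S[i0])
  }
  cand <- dds[dds$rigid_residue != 0L, , drop = FALSE]
  cand$abs_dd_S <- abs(cand$dd_S)
  hit <- cand[cand$abs_dd_S < reference_dds, , drop = FALSE]
  hit[order(hit$abs_dd_S), c("rigid_residue", "dd_S", "abs_dd_S")]
}

#' Per-residue entropic response map
#'
#' Matrix of per-residue entropy changes across a scan: element (run r,
#' residue j) is \eqn{S_j(run\,r) - S_j(unperturbed)} within one state.  The
#' unperturbed run appears as the zero row (index 0); the diagonal cells
#' (j = r) are expected strongly negative, since a rigid residue loses its
#' internal entropy.
#'
#' @param ledger an \code{EntropyLedger} whose runs carry per-residue vectors.
#' @param state state label.
#' @return Numeric matrix, rows named by rigid_residue (0 first), columns by
#'   residue.
#' @export
residue_response_map <- function(ledger, state) {
  stopifnot(inherits(ledger, "EntropyLedger"))
  tab <- ledger$table[ledger$table$state == state, , drop = FALSE]
  tab <- tab[order(tab$rigid_residue), ]
  key0 <- ledger_key(state, 0L)
  ref <- ledger$per_residue[[key0]]
  if (is.null(ref)) stop("missing per-residue vector for the unperturbed run of '", state, "'")
  rows <- lapply(tab$rigid_residue, function(r) {
    v <- ledger$per_residue[[ledger_key(state, r)]]
    if (is.null(v)) stop("missing per-residue vector for rigid residue ", r)
    v - ref
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(tab$rigid_residue, seq_along(ref))
  m
}

#' Average entropic response per residue
#'
#' Column means of a response map over the rigid runs (the unperturbed row is
#' excluded).  By default the self-rigid diagonal cells are included in the
#' average; \code{include_self = FALSE} drops them.
#'
#' @param map matrix from \code{\link{residue_response_map}}.
#' @param include_self include the (run r, residue r) cells (default TRUE).
#' @return Named numeric vector of per-residue mean responses.
#' @export
average_response <- function(map, include_self = TRUE) {
  rigid <- as.integer(rownames(map))
  m <- map[rigid != 0L, , drop = FALSE]
  if (!nrow(m)) stop("map has no rigid runs")
  if (!include_self) {
    rr <- as.integer(rownames(m))
    for (i in seq_len(nrow(m))) {
      j <- rr[i]
      if (j >= 1L && j <= ncol(m)) m[i, j] <- NA_real_
    }
  }
  colMeans(m, na.rm = TRUE)
}

#' Mean with a Student-t confidence interval
#'
#' Sample mean, sample SD (divisor n-1) and the two-sided confidence-interval
#' half-width \eqn{t_{1-\alpha/2,\,n-1}\, sd/\sqrt n}.  The default level is
#' 0.85, the convention used for trajectory-block entropy error bars.
#'
#' @param samples numeric vector, n >= 2.
#' @param level confidence level (default 0.85).
#' @return List with \code{mean}, \code{sd}, \code{half_width}, \code{n},
#'   \code{level}.
#' @export
mean_ci <- function(samples, level = 0.85) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  s <- stats::sd(samples)
  list(mean = mean(samples), sd = s,
       half_width = ci_half_width(s, n, level), n = n, level = level)
}

#' @rdname mean_ci
#' @param sd sample standard deviation.
#' @param n sample size.
#' @export
ci_half_width <- function(sd, n, level = 0.85) {
  if (any(n < 2L)) stop("need n >= 2")
  stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
}

#' Serialize / restore an entropy ledger as CSV
#'
#' The run table goes to \code{file}; per-residue vectors, when present, go to
#' a companion \code{<file>.residues.csv} in long format.
#'
#' @param ledger an \code{EntropyLedger}.
#' @param file output path.
#' @return \code{file} invisibly (\code{write_ledger_csv}); an
#'   \code{EntropyLedger} (\code{read_ledger_csv}).
#' @export
write_ledger_csv <- function(ledger, file) {
  stopifnot(inherits(ledger, "EntropyLedger"))
  utils::write.csv(ledger$table, file, row.names = FALSE)
  if (length(ledger$per_residue)) {
    long <- do.call(rbind, lapply(names(ledger$per_residue), function(k) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
      v <- ledger$per_residue[[k]]
      data.frame(state = parts[1], rigid_residue = as.integer(parts[2]),
                 resid = seq_along(v), S = v, stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, paste0(file, ".residues.csv"), row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_ledger_csv
#' @export
read_ledger_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  led <- entropy_ledger(states = unique(tab$state))
  resfile <- paste0(file, ".residues.csv")
  long <- if (file.exists(resfile)) utils::read.csv(resfile, stringsAsFactors = FALSE) else NULL
  for (i in seq_len(nrow(tab))) {
    pr <- NULL
    if (!is.null(long)) {
      sel <- long$state == tab$state[i] & long$rigid_residue == tab$rigid_residue[i]
      if (any(sel)) pr <- long$S[sel][order(long$resid[sel])]
    }
    led <- add_run(led, tab$state[i], tab$rigid_residue[i], tab$S[i],
                   per_residue = pr, n_frames = tab$n_frames[i])
  }
  led
}
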