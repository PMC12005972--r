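#' @importFrom stats median quantile sd var
#' @importFrom utils read.delim write.table head
NULL

# fluorescence channels carrying the three orthogonal HCR initiators
HCR_CHANNELS <- c(488L, 561L, 640L)

#' Barcode capacity of a split L+R readout scheme
#'
#' Each target is encoded by the combination of one left (L) and one right (R)
#' readout probe within a fluorescence channel, so a panel of `n_left` L probes
#' and `n_right` R probes encodes `n_left * n_right` targets per channel and
#' three channels triple that: 30 x 30 probes give 900 barcodes per channel and
#' 2,700 targets over three channels.
#'
#' @param n_left,n_right Number of distinct left / right readout probes.
#' @param n_channels Number of fluorescence channels (default 3).
#' @return Integer-valued count of encodable targets.
#' @examples
#' barcode_capacity(30, 30, 1)  # 900
#' barcode_capacity(30, 30, 3)  # 2700
#' @export
barcode_capacity <- function(n_left, n_right, n_channels = 3) {
  for (v in list(n_left = n_left, n_right = n_right, n_channels = n_channels)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("capacity arguments must be single non-negative numbers", call. = FALSE)
    }
  }
  as.numeric(n_left) * as.numeric(n_right) * as.numeric(n_channels)
}

#' Schedule targets over three-channel imaging cycles
#'
#' Targets are read out one per channel per cycle, filling channels first and
#' then advancing the cycle, so `ceiling(n_targets / n_channels)` cycles are
#' needed; the final cycle may be partially filled. The assignment is
#' deterministic in the input order.
#'
#' @param targets Character vector of unique target names, in readout order.
#' @param n_channels Channels per cycle (1--3; labelled 488/561/640 nm).
#' @return A `cycle_schedule`: data.frame with columns `cycle`, `channel`,
#'   `target` and attribute `n_cycles`.
#' @examples
#' sched <- schedule_cycles(paste0("g", 1:15), 3)
#' attr(sched, "n_cycles")  # 5
#' @export
schedule_cycles <- function(targets, n_channels = 3) {
  if (length(targets) == 0L) stop("'targets' must be non-empty", call. = FALSE)
  if (anyDuplicated(targets)) {
    stop("duplicate target names: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "),
         call. = FALSE)
  }
  if (n_channels < 1 || n_channels > length(HCR_CHANNELS)) {
    stop("'n_channels' must be between 1 and ", length(HCR_CHANNELS), call. = FALSE)
  }
  n <- length(targets)
  idx <- seq_len(n) - 1L
  out <- data.frame(
    cycle   = idx %/% n_channels + 1L,
    channel = HCR_CHANNELS[idx %% n_channels + 1L],
    target  = as.character(targets),
    stringsAsFactors = FALSE
  )
  attr(out, "n_cycles") <- as.integer(ceiling(n / n_channels))
  class(out) <- c("cycle_schedule", "data.frame")
  out
}

#' Build a split-barcode codebook with non-targeting controls
#'
#' Assigns each target a distinct (channel, L-index, R-index) barcode and an
#' imaging cycle. Channels and cycles follow [schedule_cycles()] over the
#' concatenation of `targets` and the generated control names; within each
#' channel, (L, R) combinations are drawn from a seed-shuffled lattice of all
#' `n_left * n_right` combinations, so the codebook is reproducible and
#' collision-free by construction. Non-targeting controls — barcode
#' combinations with no matching primary probe, used downstream to estimate
#' false-positive detection — preferentially take combinations whose L and R
#' half-sites are each used by at most one targeting entry, minimizing shared
#' half-sites with real probes.
#'
#' @param targets Character vector of gene names.
#' @param n_non_targeting Number of non-targeting control barcodes to add.
#' @param n_left,n_right Readout probe panel sizes (default 30 each).
#' @param n_channels Fluorescence channels (default 3).
#' @param seed Integer seed controlling the lattice shuffle.
#' @return A `codebook`: data.frame with columns `target`, `channel`, `cycle`,
#'   `left_index`, `right_index`, `is_control`, plus attributes `n_left`,
#'   `n_right`, `n_channels`.
#' @examples
#' cb <- build_codebook(paste0("g", 1:10), n_non_targeting = 2, seed = 1)
#' @export
build_codebook <- function(targets, n_non_targeting = 0, n_left = 30,
                           n_right = 30, n_channels = 3, seed = 1) {
  targets <- as.character(targets)
  if (anyDuplicated(targets)) stop("duplicate target names", call. = FALSE)
  n_total <- length(targets) + n_non_targeting
  if (n_total < 1L) stop("codebook must contain at least one entry", call. = FALSE)
  if (n_total > barcode_capacity(n_left, n_right, n_channels)) {
    stop(sprintf("capacity exceeded: %d entries > %d barcodes (%d x %d x %d)",
                 n_total, barcode_capacity(n_left, n_right, n_channels),
                 n_left, n_right, n_channels), call. = FALSE)
  }
  controls <- if (n_non_targeting > 0) {
    sprintf("nontargeting_%02d", seq_len(n_non_targeting))
  } else character(0)
  if (any(controls %in% targets)) {
    stop("target names collide with reserved control names", call. = FALSE)
  }

  sched <- schedule_cycles(c(targets, controls), n_channels)
  is_ctrl <- sched$target %in% controls

  lattice <- expand.grid(left_index = seq_len(n_left),
                         right_index = seq_len(n_right))
  left_idx <- integer(nrow(sched))
  right_idx <- integer(nrow(sched))
  with_seed(seed, {
    for (ch in unique(sched$channel)) {
      rows <- which(sched$channel == ch)
      lat <- lattice[sample.int(nrow(lattice)), , drop = FALSE]
      tg_rows <- rows[!is_ctrl[rows]]
      take <- seq_along(tg_rows)
      left_idx[tg_rows] <- lat$left_index[take]
      right_idx[tg_rows] <- lat$right_index[take]
      ct_rows <- rows[is_ctrl[rows]]
      if (length(ct_rows)) {
        rest <- lat[setdiff(seq_len(nrow(lat)), take), , drop = FALSE]
        # prefer combinations whose half-sites are rarely used by targets
        l_use <- tabulate(lat$left_index[take], n_left)
        r_use <- tabulate(lat$right_index[take], n_right)
        score <- l_use[rest$left_index] + r_use[rest$right_index]
        pref <- (l_use[rest$left_index] <= 1L) & (r_use[rest$right_index] <= 1L)
        ord <- order(!pref, score)
        rest <- rest[ord, , drop = FALSE]
        left_idx[ct_rows] <- rest$left_index[seq_along(ct_rows)]
        right_idx[ct_rows] <- rest$right_index[seq_along(ct_rows)]
      }
    }
  })

  cb <- data.frame(
    target = sched$target,
    channel = sched$channel,
    cycle = sched$cycle,
    left_index = left_idx,
    right_index = right_idx,
    is_control = is_ctrl,
    stringsAsFactors = FALSE
  )
  attr(cb, "n_left") <- as.integer(n_left)
  attr(cb, "n_right") <- as.integer(n_right)
  attr(cb, "n_channels") <- as.integer(n_channels)
  class(cb) <- c("codebook", "data.frame")
  validate_codebook(cb)
  cb
}

validate_codebook <- function(cb) {
  stopifnot(is.data.frame(cb),
            all(c("target", "channel", "cycle", "left_index", "right_index",
                  "is_control") %in% names(cb)))
  if (anyDuplicated(cb$target)) stop("codebook targets not unique", call. = FALSE)
  if (anyDuplicated(paste(cb$channel, cb$cycle))) {
    stop("(channel, cycle) pairs must be unique within a codebook", call. = FALSE)
  }
  if (anyDuplicated(paste(cb$channel, cb$left_index, cb$right_index))) {
    stop("(channel, L, R) barcode triples must be unique", call. = FALSE)
  }
  nl <- attr(cb, "n_left") %||% max(cb$left_index)
  nr <- attr(cb, "n_right") %||% max(cb$right_index)
  if (any(cb$left_index < 1 | cb$left_index > nl) ||
      any(cb$right_index < 1 | cb$right_index > nr)) {
    stop("barcode indices outside the declared L/R panel", call. = FALSE)
  }
  invisible(cb)
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("codebook: %d targets (%d non-targeting), %d cycles, panels %dL x %dR x %d channels\n",
              nrow(x), sum(x$is_control), max(x$cycle),
              attr(x, "n_left") %||% max(x$left_index),
              attr(x, "n_right") %||% max(x$right_index),
              length(unique(x$channel))))
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more entries\n")
  invisible(x)
}

#' Swap the barcodes of two genes
#'
#' Exchanges the full barcode (channel, cycle, L, R) between two codebook
#' entries, the control used to confirm that decoded signal tracks barcode
#' identity rather than probe position: re-imaging with a swapped codebook
#' must exchange the two genes' spatial expression patterns.
#'
#' @param codebook A [build_codebook()] result.
#' @param gene_a,gene_b Target names to exchange.
#' @return A codebook identical to the input except for the two swapped rows.
#' @export
swap_barcodes <- function(codebook, gene_a, gene_b) {
  ia <- match(gene_a, codebook$target)
  ib <- match(gene_b, codebook$target)
  if (is.na(ia)) stop("unknown gene: ", gene_a, call. = FALSE)
  if (is.na(ib)) stop("unknown gene: ", gene_b, call. = FALSE)
  out <- codebook
  cols <- c("channel", "cycle", "left_index", "right_index")
  out[c(ia, ib), cols] <- codebook[c(ib, ia), cols]
  out
}

#' Normalize a readout crosstalk matrix
#'
#' HCR amplification triggers only when both halves of a split initiator bind
#' adjacently, i.e. for the matched (L, R) readout pair. Given raw signals for
#' every L x R probe pairing and the matched-pair reference signal, returns
#' signals on a matched-pair = 1 scale so off-diagonal entries read directly
#' as fractional crosstalk.
#'
#' @param readout_signals Numeric matrix of signal per (L probe, R probe).
#' @param reference Matched-pair signal used as the unit (must be > 0).
#' @return Matrix of the same shape, normalized.
#' @export
crosstalk_matrix <- function(readout_signals, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || is.na(reference) ||
      reference <= 0) {
    stop("'reference' must be a single positive number", call. = FALSE)
  }
  readout_signals / reference
}

#' Write / read a codebook as tab-separated text
#'
#' Columns `target`, `channel`, `cycle`, `left_index`, `right_index`,
#' `is_control` with a header line; panel sizes are stored in `#` comment
#' headers so the file round-trips losslessly.
#'
#' @param codebook A codebook.
#' @param path File path (`.tsv`).
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns the codebook.
#' @export
write_codebook <- function(codebook, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_left=%d n_right=%d n_channels=%d",
                     attr(codebook, "n_left") %||% max(codebook$left_index),
                     attr(codebook, "n_right") %||% max(codebook$right_index),
                     attr(codebook, "n_channels") %||% length(unique(codebook$channel))),
             con)
  write.table(as.data.frame(codebook), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  cb <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cb$is_control <- as.logical(cb$is_control)
  if (length(meta) == 3L) {
    attr(cb, "n_left") <- meta[1]; attr(cb, "n_right") <- meta[2]
    attr(cb, "n_channels") <- meta[3]
  }
  class(cb) <- c("codebook", "data.frame")
  validate_codebook(cb)
  cb
}
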