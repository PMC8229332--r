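#' EEG montage: named channels, scalp regions, 2-D layout
#'
#' A montage assigns every channel a name, a scalp region (frontal `F`,
#' central `C`, temporal `Te`, parietal `Pa`, occipital `O`) and approximate
#' 2-D head coordinates (x toward the right ear, y toward the nasion, head
#' radius 1) for topographic export.
#'
#' @param channels character vector of channel names, in recording order.
#' @param regions character vector, one region code per channel.
#' @param xy optional numeric matrix (channels x 2) of layout coordinates.
#' @return object of class `eeg_montage`.
#' @export
make_montage <- function(channels, regions, xy = NULL) {
  stopifnot(length(channels) == length(regions), !anyDuplicated(channels))
  regions <- as.character(regions)
  bad <- setdiff(unique(regions), c("F", "C", "Te", "Pa", "O"))
  if (length(bad) > 0) {
    stop("unknown region code(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(xy)) {
    xy <- matrix(NA_real_, length(channels), 2)
  }
  stopifnot(nrow(xy) == length(channels), ncol(xy) == 2)
  rownames(xy) <- channels
  colnames(xy) <- c("x", "y")
  structure(list(channels = channels,
                 regions = stats::setNames(regions, channels),
                 xy = xy),
            class = "eeg_montage")
}

#' The 14-channel Emotiv EPOC montage
#'
#' Standard 10-20 channel names with the region assignment used throughout
#' the package: AF3, AF4, F3, F4, F7, F8 frontal; FC5, FC6 central; T7, T8
#' temporal; P7, P8 parietal; O1, O2 occipital. Layout coordinates are
#' approximate 10-20 positions on a unit head circle.
#'
#' @return an `eeg_montage` with 14 channels.
#' @export
emotiv_montage <- function() {
  ch <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
          "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  reg <- c(AF3 = "F", F7 = "F", F3 = "F", FC5 = "C", T7 = "Te", P7 = "Pa",
           O1 = "O", O2 = "O", P8 = "Pa", T8 = "Te", FC6 = "C", F4 = "F",
           F8 = "F", AF4 = "F")
  xy <- rbind(AF3 = c(-0.28, 0.85), F7 = c(-0.72, 0.55), F3 = c(-0.40, 0.58),
              FC5 = c(-0.65, 0.25), T7 = c(-0.90, 0.00), P7 = c(-0.72, -0.55),
              O1 = c(-0.28, -0.85), O2 = c(0.28, -0.85), P8 = c(0.72, -0.55),
              T8 = c(0.90, 0.00), FC6 = c(0.65, 0.25), F4 = c(0.40, 0.58),
              F8 = c(0.72, 0.55), AF4 = c(0.28, 0.85))
  make_montage(ch, reg[ch], xy[ch, ])
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("EEG montage: %d channels (%s)\n", length(x$channels),
              paste(x$channels, collapse = ", ")))
  cat("regions:", paste(sprintf("%s=%d", names(table(x$regions)),
                                table(x$regions)), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a montage as a tab-delimited table
#'
#' Columns: `channel`, `region`, and optionally `x`, `y`.
#'
#' @param path file path.
#' @rdname montage_io
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("channel", "region") %in% names(tab))) {
    stop("montage file must have 'channel' and 'region' columns: ", path)
  }
  xy <- if (all(c("x", "y") %in% names(tab))) cbind(tab$x, tab$y) else NULL
  make_montage(tab$channel, tab$region, xy)
}

#' @param montage an `eeg_montage`.
#' @rdname montage_io
#' @export
write_montage <- function(montage, path) {
  tab <- data.frame(channel = montage$channels,
                    region = unname(montage$regions[montage$channels]),
                    x = montage$xy[, "x"], y = montage$xy[, "y"])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
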