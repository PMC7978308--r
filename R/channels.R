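#' The 96 single-base-substitution trinucleotide channels
#'
#' Returns the fixed pyrimidine-centered channel axis used by every catalog
#' in the package, in COSMIC v3 ordering: the six substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G in that order, and within each class the 16
#' flanking-base combinations alphabetically (5' base fastest-varying last,
#' i.e. A[C>A]A, A[C>A]C, ..., T[C>A]T). Channel integer codes used in
#' variant tables are 0-based indices into this vector.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, r) paste0(f, "[", s, "]", r))))
  }))
}

# checksum guard: the channel axis is a wire format shared by catalogs,
# reference TSVs and the 0-95 integer codes; any reordering is a data bug
.SBS_CHANNEL_CHECKSUM <- 2620302L

assert_channel_axis <- function(channels = sbs_channels()) {
  if (length(channels) != 96L)
    stop("channel axis must have 96 entries", call. = FALSE)
  bytes <- as.integer(charToRaw(paste(channels, collapse = "")))
  chk <- sum((bytes * seq_along(bytes)) %% 7919L)
  if (chk != .SBS_CHANNEL_CHECKSUM)
    stop("channel axis does not match the COSMIC v3 ordering", call. = FALSE)
  invisible(TRUE)
}

#' Map a channel code to its reference/alternate pyrimidine bases
#'
#' @param channel Integer vector of 0-based channel codes (0-95).
#' @return Data frame with columns `ref` and `alt` (pyrimidine-strand bases).
#' @keywords internal
channel_ref_alt <- function(channel) {
  stopifnot(all(channel >= 0L & channel <= 95L))
  labs <- sbs_channels()[channel + 1L]
  data.frame(ref = substr(labs, 3, 3), alt = substr(labs, 5, 5),
             stringsAsFactors = FALSE)
}
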