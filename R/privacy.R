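# Pseudonymised public image names.

#' Pseudonymise an image filename
#'
#' Builds the public name used in every export: the registration date-time
#' followed by a four-digit decimal hash of the original filename,
#' `yymmdd-hhmm-####`. The original name itself never appears in the output,
#' so images can be shared across institutions without leaking patient
#' information embedded in filenames.
#'
#' The digest is FNV-1a (32-bit) over the UTF-8 bytes of the name, reduced
#' modulo 10000 and zero-padded: stable across sessions and platforms, with
#' no randomised hashing. Four digits cannot be injective, so collisions
#' between different names are tolerated; uniqueness within an image set is
#' enforced at registration ([register_image()]) by appending a counter.
#'
#' @param private_name Original filename.
#' @param time Timestamp fixing the `yymmdd-hhmm` prefix (`NULL` = now).
#' @return A string matching `^[0-9]{6}-[0-9]{4}-[0-9]{4}$`, deterministic in
#'   `(private_name, time)`.
#' @examples
#' pseudonymize("horse_balf_case.tif", "2021-02-23 14:05:00")
#' @export
pseudonymize <- function(private_name, time = NULL) {
  stopifnot_scalar_chr(private_name, "private_name")
  iso <- iso_now(time)
  stamp <- strftime(iso_parse(iso), "%y%m%d-%H%M", tz = "UTC")
  sprintf("%s-%04d", stamp, fnv1a32(private_name) %% 10000)
}

# FNV-1a, 32-bit, in exact double arithmetic: R has no unsigned 32-bit
# integers and naive h * 16777619 exceeds 2^53, so the multiply is split at
# 16 bits and reduced mod 2^32.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}
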