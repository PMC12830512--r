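# Acquisition-record I/O. The instrument's raw-data contract is a small CSV:
# a "# key=value" metadata header in fixed key order, a position/counts table,
# and a final "# sha256=<hex>" footprint over all preceding bytes. The format
# is byte-exact (LF newlines, UTF-8, period decimal mark) so the digest is
# platform independent. Positions are rendered in shortest exact decimal form
# (%.10g): channel centres sit at half-pitch offsets (0.25, 0.75, ... for the
# default 0.5 mm step), which a fixed one-decimal rendering would corrupt.

META_KEYS <- c("batch_number", "operator", "scan_range_mm",
               "acquisition_time_s", "origin_mm", "front_mm", "timestamp")

sha256_hex <- function(raw_bytes) {
  digest::digest(raw_bytes, algo = "sha256", serialize = FALSE)
}

# Canonical body (everything the footprint covers) as a single string.
record_body <- function(chrom) {
  md <- chrom$metadata
  meta_vals <- c(md$batch_number, md$operator,
                 fmt_num(md$scan_range_mm), fmt_num(md$acquisition_time_s),
                 fmt_num(md$origin_mm), fmt_num(md$front_mm), md$timestamp)
  lines <- c(paste0("# ", META_KEYS, "=", meta_vals),
             "position_mm,counts",
             paste0(fmt_num(chrom$positions_mm), ",",
                    sprintf("%d", chrom$counts)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialize a chromatogram to canonical record bytes
#'
#' Produces the full acquisition record: metadata header (fixed key order),
#' `position_mm,counts` table (positions to one decimal, integer counts), and
#' a closing `# sha256=` footprint line holding the SHA-256 digest of all
#' preceding bytes. LF line endings and UTF-8 encoding make the serialization
#' deterministic, so equal chromatograms always yield equal bytes.
#'
#' @param chrom A [chromatogram()].
#' @return A raw vector: the complete record including the footprint line.
#' @seealso [parse_record()], [write_record()]
#' @export
serialize_record <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  body <- charToRaw(enc2utf8(record_body(chrom)))
  footer <- charToRaw(paste0("# sha256=", sha256_hex(body), "\n"))
  c(body, footer)
}

#' Write an acquisition record to disk
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(chrom, path) {
  writeBin(serialize_record(chrom), path)
  invisible(path)
}

parse_error <- function(line_no, msg) {
  rtlc_stop(sprintf("record parse error at line %d: %s", line_no, msg),
            "rtlc_parse_error")
}

#' Parse an acquisition record
#'
#' Reads back a record produced by [serialize_record()] (or by an external
#' instrument using the same dialect) and checks its integrity footprint:
#'
#' * `"verified"` — a footprint is present and matches the SHA-256 digest of
#'   the preceding bytes;
#' * `"failed"` — a footprint is present but does not match (the file was
#'   altered after acquisition);
#' * `"unhashed"` — no footprint line (e.g. third-party instruments); the
#'   record is usable but its provenance is not protected.
#'
#' Malformed input (missing header, non-numeric fields, non-monotone
#' positions) raises a parse error naming the offending line.
#'
#' @param x A raw vector, a single string holding the record text, or a file
#'   path to read.
#' @return A list of class `acquisition_record` with elements `chromatogram`
#'   (a [chromatogram()], its `integrity` field set as above) and
#'   `footprint_hex` (64-character digest, or `NA` when absent).
#' @export
parse_record <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readBin(x, what = "raw", n = file.info(x)$size)
  }
  if (is.character(x)) x <- charToRaw(enc2utf8(paste(x, collapse = "\n")))
  if (!is.raw(x)) {
    rtlc_stop("input must be a raw vector, record text, or a file path",
              "rtlc_parse_error")
  }
  txt <- rawToChar(x)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    rtlc_stop("record is not valid UTF-8", "rtlc_parse_error")
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]

  # Footprint: last non-empty line, if it is a sha256 comment.
  footprint <- NA_character_
  integrity <- "unhashed"
  n_lines <- length(lines)
  foot_idx <- NA_integer_
  if (n_lines > 0 && grepl("^# sha256=", lines[n_lines])) {
    foot_idx <- n_lines
    footprint <- sub("^# sha256=", "", lines[n_lines])
    if (!grepl("^[0-9a-f]{64}$", footprint)) {
      parse_error(n_lines, "malformed sha256 footprint")
    }
    # Digest spans every byte up to (and including) the newline that
    # precedes the footprint line.
    nl <- which(x == as.raw(0x0a))
    start_of_last <- if (length(nl) >= 2) nl[length(nl) - 1L] else 0L
    if (x[length(x)] != as.raw(0x0a)) {
      # footprint line unterminated: last newline starts it
      start_of_last <- if (length(nl) >= 1) nl[length(nl)] else 0L
    }
    hashed <- x[seq_len(start_of_last)]
    integrity <- if (identical(sha256_hex(hashed), footprint)) "verified" else "failed"
    lines <- lines[-foot_idx]
  }

  meta <- list()
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") next
    if (grepl("^# ", ln)) {
      kv <- sub("^# ", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 1) parse_error(i, "metadata line without '='")
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    } else if (ln == "position_mm,counts") {
      header_at <- i
      break
    } else {
      parse_error(i, sprintf("unexpected line before header: '%s'", ln))
    }
  }
  if (is.na(header_at)) {
    rtlc_stop("record has no 'position_mm,counts' header line",
              "rtlc_parse_error")
  }
  missing <- setdiff(META_KEYS, names(meta))
  if (length(missing) > 0) {
    rtlc_stop(paste0("record metadata is missing key(s): ",
                     paste(missing, collapse = ", ")), "rtlc_parse_error")
  }

  data_lines <- lines[seq.int(header_at + 1L, length.out = length(lines) - header_at)]
  keep <- data_lines != ""
  data_lines <- data_lines[keep]
  line_nos <- (header_at + seq_along(keep))[keep]
  if (length(data_lines) == 0) {
    rtlc_stop("record contains no data rows", "rtlc_parse_error")
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) parse_error(line_nos[bad[1]], "expected 'position,counts'")
  pos <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(pos)) parse_error(line_nos[which(is.na(pos))[1]], "non-numeric position")
  if (anyNA(cnt)) parse_error(line_nos[which(is.na(cnt))[1]], "non-numeric counts")
  if (any(cnt != round(cnt)) || any(cnt < 0)) {
    parse_error(line_nos[which(cnt != round(cnt) | cnt < 0)[1]],
                "counts must be non-negative integers")
  }
  if (length(pos) > 1 && any(diff(pos) <= 0)) {
    parse_error(line_nos[which(diff(pos) <= 0)[1] + 1L],
                "positions must be strictly increasing")
  }

  num <- function(key, line_hint) {
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (is.na(v)) {
      rtlc_stop(sprintf("metadata key '%s' is not numeric", key),
                "rtlc_parse_error")
    }
    v
  }
  md <- acquisition_metadata(batch_number = meta$batch_number,
                             operator = meta$operator,
                             scan_range_mm = num("scan_range_mm"),
                             acquisition_time_s = num("acquisition_time_s"),
                             origin_mm = num("origin_mm"),
                             front_mm = num("front_mm"),
                             timestamp = meta$timestamp)
  dwell <- md$acquisition_time_s / length(pos)
  chrom <- chromatogram(pos, cnt, dwell, md, integrity = integrity)
  structure(list(chromatogram = chrom, footprint_hex = footprint),
            class = "acquisition_record")
}

#' Read an acquisition record from a file
#'
#' Convenience wrapper around [parse_record()].
#'
#' @param path Path to a record CSV.
#' @return An `acquisition_record` (see [parse_record()]).
#' @export
read_record <- function(path) {
  if (!file.exists(path)) {
    rtlc_stop(sprintf("no such file: %s", path), "rtlc_parse_error")
  }
  parse_record(readBin(path, what = "raw", n = file.info(path)$size))
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf("<acquisition_record> integrity=%s footprint=%s\n",
              x$chromatogram$integrity,
              if (is.na(x$footprint_hex)) "<absent>"
              else paste0(substr(x$footprint_hex, 1, 12), "...")))
  print(x$chromatogram)
  invisible(x)
}
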