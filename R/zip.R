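# Minimal ZIP container writer.
#
# Spreadsheet workbooks are ZIP archives; R ships an unzipper but no
# zipper, so archives are assembled by hand here. Entries are
# DEFLATE-compressed by routing each payload through a gzip connection and
# harvesting the raw deflate stream plus the CRC32 the gzip trailer
# already carries (gzip = 10-byte header [flags 0] + deflate stream +
# CRC32 + size).

# compress raw payload; returns list(deflate, crc, size)
deflate_raw <- function(payload) {
  tf <- tempfile(fileext = ".gz")
  on.exit(unlink(tf))
  con <- gzfile(tf, "wb")
  writeBin(payload, con)
  close(con)
  gz <- readBin(tf, "raw", file.info(tf)$size)
  n <- length(gz)
  if (n < 19L || gz[1] != as.raw(0x1f) || gz[2] != as.raw(0x8b) ||
      gz[4] != as.raw(0))
    stop("unexpected gzip framing")   # header with flags 0 assumed
  crc <- sum(as.numeric(gz[(n - 7L):(n - 4L)]) * 256^(0:3))
  list(deflate = gz[11:(n - 8L)], crc = crc, size = length(payload))
}

u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                            (x %/% 256^2) %% 256, (x %/% 256^3) %% 256))

# files: named list of raw vectors (names are archive paths, '/'-separated)
zip_write <- function(files, path) {
  stopifnot(length(files) >= 1L, !is.null(names(files)))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  entries <- vector("list", length(files))
  pos <- 0
  for (i in seq_along(files)) {
    nm <- charToRaw(names(files)[i])
    d <- deflate_raw(files[[i]])
    local_hdr <- c(u32(0x04034b50), u16(20L), u16(0L), u16(8L),
                   u16(0L), u16(0x21), # fixed DOS time/date: reproducible
                   u32(d$crc), u32(length(d$deflate)), u32(d$size),
                   u16(length(nm)), u16(0L), nm)
    writeBin(local_hdr, con)
    writeBin(d$deflate, con)
    offsets[i] <- pos
    pos <- pos + length(local_hdr) + length(d$deflate)
    entries[[i]] <- c(u32(0x02014b50), u16(20L), u16(20L), u16(0L),
                      u16(8L), u16(0L), u16(0x21),
                      u32(d$crc), u32(length(d$deflate)), u32(d$size),
                      u16(length(nm)), u16(0L), u16(0L), u16(0L), u16(0L),
                      u32(0L), u32(offsets[i]), nm)
  }
  cd <- do.call(c, entries)
  writeBin(cd, con)
  writeBin(c(u32(0x06054b50), u16(0L), u16(0L),
             u16(length(files)), u16(length(files)),
             u32(length(cd)), u32(pos), u16(0L)), con)
  invisible(path)
}
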