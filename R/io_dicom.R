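#' Read a DICOM RT-DOSE file
#'
#' Minimal reader for explicit-VR little-endian RT-DOSE objects: returns
#' the dose grid with the dose-grid-scaling factor applied, together with
#' pixel spacing, frame offsets and the grid origin.  Only the attributes
#' a dose grid needs are interpreted; everything else is skipped.  The
#' result feeds [resample_grid()].
#'
#' @param path DICOM file path.
#' @return list with `dose` (rows x columns x frames array, scaled),
#'   `rows`, `cols`, `frames`, `spacing` (row, col, mm), `origin`
#'   (image position patient), `frame_offsets`, `scaling`.
#' @export
read_rtdose <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", 1, 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", 1, 4,
                              endian = "little")
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (len < 0 || data_at + len - 1 > length(raw))
      stop("corrupt DICOM element at byte ", pos)
    key <- sprintf("%04x,%04x", group, elem)
    elems[[key]] <- list(vr = vr, data = raw[data_at:(data_at + len - 1L)])
    pos <- data_at + len
  }
  need <- function(key, what) {
    if (is.null(elems[[key]]))
      stop("RT-DOSE attribute missing: ", what, " (", key, ")")
    elems[[key]]
  }
  str_of <- function(e) trimws(rawToChar(e$data))
  nums_of <- function(e) as.numeric(strsplit(str_of(e), "\\\\")[[1]])
  ts <- str_of(need("0002,0010", "TransferSyntaxUID"))
  if (ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax (only explicit VR little endian): ", ts)
  modality <- str_of(need("0008,0060", "Modality"))
  if (modality != "RTDOSE")
    stop("not an RT-DOSE object (Modality = ", modality, ")")
  rows <- readBin(need("0028,0010", "Rows")$data, "integer", 1, 2,
                  signed = FALSE, endian = "little")
  cols <- readBin(need("0028,0011", "Columns")$data, "integer", 1, 2,
                  signed = FALSE, endian = "little")
  frames <- if (!is.null(elems[["0028,0008"]]))
    as.integer(str_of(elems[["0028,0008"]])) else 1L
  bits <- readBin(need("0028,0100", "BitsAllocated")$data, "integer", 1, 2,
                  signed = FALSE, endian = "little")
  if (!bits %in% c(16L, 32L)) stop("unsupported BitsAllocated: ", bits)
  scaling <- as.numeric(str_of(need("3004,000e", "DoseGridScaling")))
  spacing <- nums_of(need("0028,0030", "PixelSpacing"))
  origin <- if (!is.null(elems[["0020,0032"]]))
    nums_of(elems[["0020,0032"]]) else c(0, 0, 0)
  offsets <- if (!is.null(elems[["3004,000c"]]))
    nums_of(elems[["3004,000c"]]) else seq_len(frames) - 1
  px <- need("7fe0,0010", "PixelData")
  stored <- readBin(px$data, "integer", rows * cols * frames, bits / 8,
                    signed = FALSE, endian = "little")
  if (length(stored) != rows * cols * frames)
    stop("PixelData length does not match Rows*Columns*Frames")
  dose <- array(stored * scaling, dim = c(cols, rows, frames)) # col fastest
  dose <- aperm(dose, c(2, 1, 3))
  list(dose = dose, rows = rows, cols = cols, frames = frames,
       spacing = spacing, origin = origin, frame_offsets = offsets,
       scaling = scaling)
}
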