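#' Decode barcodes from a specimen image by vector-assisted region proposal
#'
#' The full pipeline: detect rectangle-like contours, propose one extended
#' scan vector per rectangle, concatenate the sampled scanlines into a small
#' composite image, and decode the composite column-wise with the line
#' scanner (including its contrast/brightness fallback loop). Rotation of
#' the barcode in the source image does not matter: contours are found at
#' any orientation and each vector is sampled along its own axis.
#'
#' @param x A [gray_image] or a path to a JPEG/PNG/TIFF file.
#' @param proposal A [proposal_config].
#' @param decoder A [decoder_config].
#' @return A list of class `varp_result`: `decoded` (data frame of decoded
#'   barcodes), `n_vectors` (number of proposal vectors), `reduction`
#'   (resolution-reduction fraction, `NA` when no vectors were proposed).
#' @examples
#' spec <- synthetic_spec("UCHT00123456", "code128", image_size = c(1200, 1600),
#'                        rotation_deg = 30, seed = 7)
#' img <- render_specimen(spec)$image
#' varp_decode(img)$decoded$value  # "UCHT00123456"
#' @export
varp_decode <- function(x, proposal = proposal_config(),
                        decoder = decoder_config()) {
  img <- if (inherits(x, "gray_image")) x else load_grayscale(x)
  vecs <- propose_vectors(img, proposal)
  comp <- build_composite(img, vecs)
  decoded <- decode_composite(comp, decoder)
  structure(list(decoded = decoded, n_vectors = length(vecs),
                 reduction = if (is.null(comp)) NA_real_
                             else resolution_reduction(img, comp)),
            class = "varp_result")
}

#' @export
print.varp_result <- function(x, ...) {
  cat(sprintf("<varp_result: %d vector(s), %d decode(s)%s>\n",
              x$n_vectors, nrow(x$decoded),
              if (is.na(x$reduction)) ""
              else sprintf(", %.1f%% reduction", 100 * x$reduction)))
  if (nrow(x$decoded)) print(x$decoded)
  invisible(x)
}
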