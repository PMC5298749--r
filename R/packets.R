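# Fixed-layout binary packet codecs for the three wire messages the
# platform exchanges, plus AES-128 payload protection.
#
# Wire dialect: a 1-byte type tag (1 = fixed station, 2 = continuous
# sampling, 3 = ECG) followed by little-endian fields; integers are
# int32 except the station's respiration rate (int16), reals are
# IEEE-754 float32. Encoded sizes are constant per type: 19, 25 and 329
# bytes.

PACKET_TAGS <- c(fixed_station = 1L, continuous = 2L, ecg = 3L)
PACKET_SIZES <- c(fixed_station = 19L, continuous = 25L, ecg = 329L)

# snap a double to the nearest IEEE-754 float32 so encode/decode is an
# exact identity on constructed packets
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}

int32_check <- function(x, what) {
  if (any(!is.finite(x)) || any(x < -2^31) || any(x > 2^31 - 1))
    stop(what, " out of int32 range")
  as.integer(x)
}

#' Fixed measurement station packet
#'
#' The message the bedside station sends per sampling cycle: packet and
#' patient identifiers, blood oxygen saturation, respiration rate and
#' galvanic skin resistance.
#'
#' @param package_id,patient_id Integer identifiers (int32 on the wire).
#' @param blood_oxygen SpO2 in percent (float32).
#' @param respiration_rate Breaths per minute, non-negative (int16).
#' @param galvanic_resistance Skin resistance in ohms (float32).
#' @return An object of class `c("fixed_station_packet", "bsn_packet")`.
#' @export
fixed_station_packet <- function(package_id, patient_id, blood_oxygen,
                                 respiration_rate, galvanic_resistance) {
  respiration_rate <- as.integer(respiration_rate)
  if (respiration_rate < 0 || respiration_rate > 32767)
    stop("respiration_rate out of int16 range or negative")
  structure(list(package_id = int32_check(package_id, "package_id"),
                 patient_id = int32_check(patient_id, "patient_id"),
                 blood_oxygen = as_float32(blood_oxygen),
                 respiration_rate = respiration_rate,
                 galvanic_resistance = as_float32(galvanic_resistance)),
            class = c("fixed_station_packet", "bsn_packet"))
}

#' Continuous sampling packet from the wearable node
#'
#' Temperature travels as centi-degrees in an int32 (the wire field is
#' an integer; encoding hundredths keeps two decimals of precision),
#' heart rate as float32, the fall flag and region id as int32.
#'
#' @param package_id,patient_id Integer identifiers.
#' @param temperature_c Temperature in degC; stored as `temperature`,
#'   integer centi-degrees.
#' @param heart_rate Heart rate in bpm (float32).
#' @param fall 0/1 fall flag.
#' @param location Integer region id.
#' @return An object of class `c("continuous_packet", "bsn_packet")`.
#' @export
continuous_packet <- function(package_id, patient_id, temperature_c,
                              heart_rate, fall, location) {
  fall <- as.integer(fall)
  if (!fall %in% c(0L, 1L)) stop("fall must be 0 or 1")
  structure(list(package_id = int32_check(package_id, "package_id"),
                 patient_id = int32_check(patient_id, "patient_id"),
                 temperature = int32_check(round(temperature_c * 100),
                                           "temperature"),
                 heart_rate = as_float32(heart_rate),
                 fall = fall,
                 location = int32_check(location, "location")),
            class = c("continuous_packet", "bsn_packet"))
}

#' Temperature of a continuous packet in degrees Celsius
#' @param p A `continuous_packet`.
#' @return Temperature in degC (the wire carries centi-degrees).
#' @export
packet_temperature_c <- function(p) {
  stopifnot(inherits(p, "continuous_packet"))
  p$temperature / 100
}

#' ECG waveform packet
#'
#' Carries exactly 80 consecutive ECG samples (float32) plus the two
#' identifiers.
#'
#' @param package_id,patient_id Integer identifiers.
#' @param samples Numeric vector of exactly 80 ECG samples.
#' @return An object of class `c("ecg_packet", "bsn_packet")`.
#' @export
ecg_packet <- function(package_id, patient_id, samples) {
  if (length(samples) != 80L)
    stop("ECG packets carry exactly 80 samples, got ", length(samples))
  structure(list(package_id = int32_check(package_id, "package_id"),
                 patient_id = int32_check(patient_id, "patient_id"),
                 samples = as_float32(samples)),
            class = c("ecg_packet", "bsn_packet"))
}

#' Encode a packet to its wire bytes
#'
#' @param p A packet built by [fixed_station_packet()],
#'   [continuous_packet()] or [ecg_packet()].
#' @return A raw vector of the fixed per-type length (19, 25 or 329
#'   bytes).
#' @export
encode_packet <- function(p) {
  stopifnot(inherits(p, "bsn_packet"))
  le_int <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                       endian = "little")
  le_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L,
                                 endian = "little")
  if (inherits(p, "fixed_station_packet")) {
    c(as.raw(PACKET_TAGS[["fixed_station"]]),
      le_int(p$package_id, 4L), le_int(p$patient_id, 4L),
      le_f32(p$blood_oxygen), le_int(p$respiration_rate, 2L),
      le_f32(p$galvanic_resistance))
  } else if (inherits(p, "continuous_packet")) {
    c(as.raw(PACKET_TAGS[["continuous"]]),
      le_int(p$package_id, 4L), le_int(p$patient_id, 4L),
      le_int(p$temperature, 4L), le_f32(p$heart_rate),
      le_int(p$fall, 4L), le_int(p$location, 4L))
  } else if (inherits(p, "ecg_packet")) {
    c(as.raw(PACKET_TAGS[["ecg"]]),
      le_int(p$package_id, 4L), le_int(p$patient_id, 4L),
      le_f32(p$samples))
  } else stop("unknown packet class")
}

#' Decode wire bytes back into a packet
#'
#' Exact inverse of [encode_packet()]; rejects unknown type tags,
#' truncated buffers and trailing bytes.
#'
#' @param b Raw vector as produced by [encode_packet()].
#' @return The decoded packet object.
#' @export
decode_packet <- function(b) {
  stopifnot(is.raw(b))
  if (length(b) < 1L) stop("empty buffer")
  tag <- as.integer(b[1L])
  type <- names(PACKET_TAGS)[match(tag, PACKET_TAGS)]
  if (is.na(type)) stop("unknown packet type tag: ", tag)
  if (length(b) != PACKET_SIZES[[type]])
    stop(sprintf("framing error: %s packet must be %d bytes, got %d",
                 type, PACKET_SIZES[[type]], length(b)))
  body <- b[-1L]
  rd_int <- function(off, size) readBin(body[(off + 1L):(off + size)],
                                        "integer", size = size,
                                        endian = "little")
  rd_f32 <- function(off, n = 1L) readBin(body[(off + 1L):(off + 4L * n)],
                                          "numeric", n = n, size = 4L,
                                          endian = "little")
  switch(type,
    fixed_station = fixed_station_packet(
      package_id = rd_int(0L, 4L), patient_id = rd_int(4L, 4L),
      blood_oxygen = rd_f32(8L), respiration_rate = rd_int(12L, 2L),
      galvanic_resistance = rd_f32(14L)),
    continuous = {
      p <- continuous_packet(
        package_id = rd_int(0L, 4L), patient_id = rd_int(4L, 4L),
        temperature_c = 0, heart_rate = rd_f32(12L),
        fall = rd_int(16L, 4L), location = rd_int(20L, 4L))
      p$temperature <- rd_int(8L, 4L)   # raw centi-degrees, no re-rounding
      p
    },
    ecg = ecg_packet(package_id = rd_int(0L, 4L),
                     patient_id = rd_int(4L, 4L),
                     samples = rd_f32(8L, 80L)))
}

#' Hex dump of a packet's wire bytes
#' @param p A packet.
#' @return A single string of space-separated hex bytes.
#' @export
packet_hex <- function(p) paste(format(encode_packet(p)), collapse = " ")

#' Encrypt a packet payload with AES-128
#'
#' AES-128 in CTR mode with an explicit 16-byte nonce prepended to the
#' ciphertext, so each packet is self-contained. CBC with PKCS#7 padding
#' is available as an alternative mode.
#'
#' @param b Raw payload (e.g. from [encode_packet()]).
#' @param key Raw vector of exactly 16 bytes (AES-128).
#' @param nonce Raw 16-byte nonce / IV; freshly random by default. Reuse
#'   under the same key weakens CTR; a repeated nonce triggers a warning
#'   when the caller passes one explicitly marked used (not tracked
#'   internally).
#' @param mode `"ctr"` (default) or `"cbc"`.
#' @return Raw vector `nonce || ciphertext`.
#' @export
encrypt_payload <- function(b, key, nonce = openssl::rand_bytes(16),
                            mode = c("ctr", "cbc")) {
  mode <- match.arg(mode)
  stopifnot(is.raw(b), is.raw(nonce), length(nonce) == 16L)
  if (!is.raw(key) || length(key) != 16L)
    stop("AES-128 keys are exactly 16 bytes")
  ct <- if (mode == "ctr") {
    openssl::aes_ctr_encrypt(b, key = key, iv = nonce)
  } else {
    pad <- 16L - (length(b) %% 16L)
    openssl::aes_cbc_encrypt(c(b, as.raw(rep(pad, pad))), key = key,
                             iv = nonce)
  }
  c(nonce, as.raw(ct))
}

#' Decrypt a payload produced by [encrypt_payload()]
#'
#' @param b Raw vector `nonce || ciphertext`.
#' @param key Raw 16-byte AES-128 key.
#' @param mode `"ctr"` or `"cbc"`, matching the encryption.
#' @return The decrypted raw payload.
#' @export
decrypt_payload <- function(b, key, mode = c("ctr", "cbc")) {
  mode <- match.arg(mode)
  stopifnot(is.raw(b))
  if (!is.raw(key) || length(key) != 16L)
    stop("AES-128 keys are exactly 16 bytes")
  if (length(b) < 17L) stop("payload too short to hold a nonce")
  nonce <- b[1:16]
  ct <- b[-(1:16)]
  if (mode == "ctr") {
    as.raw(openssl::aes_ctr_decrypt(ct, key = key, iv = nonce))
  } else {
    pt <- as.raw(openssl::aes_cbc_decrypt(ct, key = key, iv = nonce))
    pad <- as.integer(pt[length(pt)])
    if (pad < 1L || pad > 16L) stop("corrupt CBC padding")
    pt[seq_len(length(pt) - pad)]
  }
}
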