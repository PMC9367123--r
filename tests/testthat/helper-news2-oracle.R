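# Independently transcribed NEWS-2 chart (Royal College of Physicians
# banding), written as literal if-chains. Deliberately does NOT read the
# package's band-table resource: it is the oracle the table-driven
# scorer is checked against.

oracle_rr <- function(v) {
  v <- round(v)
  if (v <= 8) 3L else if (v <= 11) 1L else if (v <= 20) 0L
  else if (v <= 24) 2L else 3L
}

oracle_spo2_scale1 <- function(v) {
  v <- round(v)
  if (v <= 91) 3L else if (v <= 93) 2L else if (v <= 95) 1L else 0L
}

oracle_spo2_scale2 <- function(v, on_oxygen) {
  v <- round(v)
  if (v <= 83) 3L else if (v <= 85) 2L else if (v <= 87) 1L
  else if (v <= 92) 0L
  else if (!on_oxygen) 0L
  else if (v <= 94) 1L else if (v <= 96) 2L else 3L
}

oracle_o2 <- function(on_oxygen) if (on_oxygen) 2L else 0L

oracle_sbp <- function(v) {
  v <- round(v)
  if (v <= 90) 3L else if (v <= 100) 2L else if (v <= 110) 1L
  else if (v <= 219) 0L else 3L
}

oracle_hr <- function(v) {
  v <- round(v)
  if (v <= 40) 3L else if (v <= 50) 1L else if (v <= 90) 0L
  else if (v <= 110) 1L else if (v <= 130) 2L else 3L
}

oracle_acvpu <- function(level) if (level == "Alert") 0L else 3L

oracle_temp <- function(v) {
  v <- round(v, 1)
  if (v <= 35.0) 3L else if (v <= 36.0) 1L else if (v <= 38.0) 0L
  else if (v <= 39.0) 1L else 2L
}

news2_oracle <- function(rr, spo2, on_oxygen, sbp, hr, acvpu, temp,
                         scale2 = FALSE) {
  comp <- c(
    resp_rate = oracle_rr(rr),
    spo2 = if (scale2) oracle_spo2_scale2(spo2, on_oxygen)
           else oracle_spo2_scale1(spo2),
    supplemental_o2 = oracle_o2(on_oxygen),
    sbp = oracle_sbp(sbp),
    heart_rate = oracle_hr(hr),
    consciousness = oracle_acvpu(acvpu),
    temperature = oracle_temp(temp))
  c(comp, total = sum(comp))
}
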