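# Independently coded single-photon-loop reference implementation of the
# photon transport, consuming the exact random stream of the compiled
# engine (via mc_rng_stream). Used to verify the engine number for number.

mc_oracle <- function(model, source = mc_source(),
                      detector = mc_detector_annulus(source),
                      n_photons, seed, w_threshold = 1e-4, p_survive = 0.1,
                      max_steps = 1e6, stream_size = 2e6) {
  df <- as.data.frame(model)
  z0 <- cumsum(c(0, df$thickness[-nrow(df)])) / 10
  z1v <- z0 + df$thickness / 10
  mua <- df$mua; mus <- df$mus; gv <- df$g
  mut <- mua + mus
  inv_mut <- ifelse(mut > 0, 1 / mut, 0)
  af <- ifelse(mut > 0, mua / mut, 0)
  nl <- length(mua)
  zb <- z1v[nl]
  n_tissue <- df$n[1]
  n_amb <- attr(model, "n_ambient")
  if (is.null(n_amb)) n_amb <- tissue_optics()$n_ambient
  matched <- abs(n_tissue - n_amb) < 1e-12
  side <- source$side / 10
  det_in <- detector$inner / 10
  det_out <- detector$outer / 10
  det_bottom <- detector$surface == "bottom"

  u <- mc_rng_stream(seed, stream_size)
  ui <- 0L
  nxt <- function() {
    ui <<- ui + 1L
    if (ui > length(u)) stop("oracle stream exhausted")
    u[ui]
  }

  fresnel <- function(ni, nt, ci) {
    if (ci > 1) ci <- 1
    si <- sqrt(max(0, 1 - ci * ci))
    st <- si * ni / nt
    if (st >= 1) return(1)
    ct <- sqrt(max(0, 1 - st * st))
    if (si < 1e-12) {
      r <- (ni - nt) / (ni + nt)
      return(r * r)
    }
    rs <- (ni * ci - nt * ct) / (ni * ci + nt * ct)
    rp <- (ni * ct - nt * ci) / (ni * ct + nt * ci)
    0.5 * (rs * rs + rp * rp)
  }

  sin_max <- sin(min(source$half_angle, pi / 2))
  sin2_max <- sin_max * sin_max

  detected <- 0; escaped <- 0; absorbed <- 0; bottom <- 0; rnet <- 0
  n_det <- 0L

  for (ph in seq_len(n_photons)) {
    u1 <- nxt(); u2 <- nxt()
    x <- (u1 - 0.5) * side; y <- (u2 - 0.5) * side; z <- 0
    u3 <- nxt(); u4 <- nxt()
    si <- sqrt(u3 * sin2_max)
    ci <- sqrt(1 - si * si)
    phi <- 2 * pi * u4
    w <- 1
    if (matched) {
      ux <- si * cos(phi); uy <- si * sin(phi); uz <- ci
    } else {
      R <- fresnel(n_amb, n_tissue, ci)
      escaped <- escaped + R
      w <- 1 - R
      st <- si * n_amb / n_tissue
      ct <- sqrt(max(0, 1 - st * st))
      ux <- st * cos(phi); uy <- st * sin(phi); uz <- ct
    }
    inv_uz <- if (uz != 0) 1 / uz else 0

    lay <- 1L
    alive <- TRUE
    steps <- 0
    while (alive) {
      steps <- steps + 1
      if (steps > max_steps) {
        absorbed <- absorbed + w
        break
      }
      s <- -log(nxt())
      while (s > 0) {
        db <- if (uz > 0) (z1v[lay] - z) * inv_uz
              else if (uz < 0) (z0[lay] - z) * inv_uz
              else Inf
        ds <- db * mut[lay]
        if (ds <= s) {
          if (is.finite(db)) {
            x <- x + ux * db
            y <- y + uy * db
          }
          s <- s - ds
          if (uz < 0 && lay == 1L && z0[1] <= 0) {
            z <- 0
            if (matched) {
              r <- sqrt(x * x + y * y)
              if (!det_bottom && r >= det_in && r <= det_out) {
                detected <- detected + w
                n_det <- n_det + 1L
              } else escaped <- escaped + w
              alive <- FALSE
              break
            }
            R <- fresnel(n_tissue, n_amb, -uz)
            Tr <- 1 - R
            if (Tr > 0) {
              r <- sqrt(x * x + y * y)
              if (!det_bottom && r >= det_in && r <= det_out) {
                detected <- detected + w * Tr
                n_det <- n_det + 1L
              } else escaped <- escaped + w * Tr
            }
            w <- w * R
            uz <- -uz
            inv_uz <- -inv_uz
            if (w <= 0) { alive <- FALSE; break }
          } else if (uz > 0 && lay == nl && z1v[nl] >= zb) {
            z <- zb
            r <- sqrt(x * x + y * y)
            if (det_bottom && r >= det_in && r <= det_out) {
              detected <- detected + w
              n_det <- n_det + 1L
            } else bottom <- bottom + w
            alive <- FALSE
            break
          } else {
            if (uz > 0) { z <- z1v[lay]; lay <- lay + 1L }
            else { z <- z0[lay]; lay <- lay - 1L }
          }
        } else {
          d <- s * inv_mut[lay]
          x <- x + ux * d; y <- y + uy * d; z <- z + uz * d
          s <- 0
          dep <- w * af[lay]
          absorbed <- absorbed + dep
          w <- w - dep
          if (w <= 0 || mus[lay] <= 0) {
            absorbed <- absorbed + w
            w <- 0
            alive <- FALSE
            break
          }
          g <- gv[lay]
          u5 <- nxt(); u6 <- nxt()
          if (abs(g) > 1e-12) {
            tmp <- (1 - g * g) / (1 - g + 2 * g * u5)
            ct <- (1 + g * g - tmp * tmp) / (2 * g)
          } else ct <- 2 * u5 - 1
          ct <- min(1, max(-1, ct))
          st <- sqrt(1 - ct * ct)
          psi <- 2 * pi * u6
          cp <- cos(psi); sp <- sin(psi)
          if (abs(uz) > 0.99999) {
            ux <- st * cp; uy <- st * sp
            uz <- if (uz >= 0) ct else -ct
          } else {
            den <- sqrt(1 - uz * uz)
            inv_den <- 1 / den
            nux <- st * (ux * uz * cp - uy * sp) * inv_den + ux * ct
            nuy <- st * (uy * uz * cp + ux * sp) * inv_den + uy * ct
            nuz <- -den * st * cp + uz * ct
            ux <- nux; uy <- nuy; uz <- nuz
          }
          inv_uz <- if (uz != 0) 1 / uz else 0
        }
      }
      if (!alive) break
      if (w < w_threshold) {
        u7 <- nxt()
        if (u7 < p_survive) {
          w_new <- w / p_survive
          rnet <- rnet + (w_new - w)
          w <- w_new
        } else {
          rnet <- rnet - w
          alive <- FALSE
        }
      }
    }
  }
  list(detected_fraction = detected / n_photons,
       escaped_fraction = escaped / n_photons,
       absorbed_fraction = (absorbed + bottom - rnet) / n_photons,
       n_detected_photons = n_det,
       uniforms_used = ui)
}
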