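## Presentation-only HTML rendering of a player report. Every number shown
## comes straight from the report object; drawing never recomputes or
## rounds beyond display formatting.

BIN_COLORS <- c(green = "#2e9e4f", yellow = "#e3c800", orange = "#e8821e",
                red = "#d43a3a")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt <- function(x, d = 1) formatC(x, format = "f", digits = d)

# speedometer: seven colored arcs, needle at the dial index
svg_speedometer <- function(dial, label) {
  if (is.na(dial)) return(sprintf("<div class='dial'>%s: n/a</div>", label))
  cols <- BIN_COLORS[c("red", "orange", "yellow", "green", "yellow",
                       "orange", "red")]
  segs <- character(7)
  for (i in 0:6) {
    a0 <- pi - i * pi / 7; a1 <- pi - (i + 1) * pi / 7
    segs[i + 1] <- sprintf(
      "<path d='M %.1f %.1f A 40 40 0 0 1 %.1f %.1f' stroke='%s' stroke-width='12' fill='none'/>",
      60 + 40 * cos(a0), 55 - 40 * sin(a0),
      60 + 40 * cos(a1), 55 - 40 * sin(a1), cols[i + 1])
  }
  ang <- pi - (dial + 3.5) * pi / 7
  needle <- sprintf(
    "<line x1='60' y1='55' x2='%.1f' y2='%.1f' stroke='black' stroke-width='2'/>",
    60 + 34 * cos(ang), 55 - 34 * sin(ang))
  sprintf("<div class='dial'><svg width='120' height='64'>%s%s</svg><br/>%s (dial %+d)</div>",
          paste(segs, collapse = ""), needle, html_escape(label), dial)
}

# horizontal asymmetry bar with the four score bands and a marker at pct
svg_asym_bar <- function(joint, pct, score, extreme) {
  w <- function(p) 2 * min(p, 100)
  bands <- sprintf(
    paste0("<rect x='0' width='%.0f' y='6' height='14' fill='%s'/>",
           "<rect x='%.0f' width='%.0f' y='6' height='14' fill='%s'/>",
           "<rect x='%.0f' width='%.0f' y='6' height='14' fill='%s'/>",
           "<rect x='%.0f' width='%.0f' y='6' height='14' fill='%s'/>"),
    w(20), BIN_COLORS["green"], w(20), w(50) - w(20), BIN_COLORS["yellow"],
    w(50), w(70) - w(50), BIN_COLORS["orange"], w(70), 200 - w(70),
    BIN_COLORS["red"])
  marker <- sprintf(
    "<line x1='%.1f' x2='%.1f' y1='2' y2='24' stroke='blue' stroke-width='3'/>",
    w(pct), w(pct))
  star <- if (isTRUE(extreme)) " *" else ""
  sprintf("<div>%s: %s%% (AS=%d)%s<br/><svg width='210' height='26'>%s%s</svg></div>",
          html_escape(joint), fmt(pct), score, star, bands, marker)
}

# pie of nine factor slices colored by percent-of-trials-at-risk bin
svg_risk_pie <- function(factors) {
  n <- nrow(factors)
  slices <- character(n)
  for (i in seq_len(n)) {
    a0 <- 2 * pi * (i - 1) / n - pi / 2
    a1 <- 2 * pi * i / n - pi / 2
    col <- BIN_COLORS[[factors$color_bin[i]]]
    mid <- (a0 + a1) / 2
    slices[i] <- sprintf(
      paste0("<path d='M 70 70 L %.1f %.1f A 60 60 0 0 1 %.1f %.1f Z' ",
             "fill='%s' stroke='white'/>",
             "<text x='%.1f' y='%.1f' font-size='9' text-anchor='middle'>%s</text>"),
      70 + 60 * cos(a0), 70 + 60 * sin(a0),
      70 + 60 * cos(a1), 70 + 60 * sin(a1), col,
      70 + 42 * cos(mid), 70 + 42 * sin(mid),
      html_escape(factors$factor_id[i]))
  }
  sprintf("<svg width='140' height='140'>%s</svg>", paste(slices, collapse = ""))
}

svg_dashboard <- function(category_red) {
  lights <- vapply(names(category_red), function(cat) {
    col <- if (isTRUE(category_red[[cat]])) BIN_COLORS[["red"]]
    else BIN_COLORS[["green"]]
    sprintf("<span style='display:inline-block;width:18px;height:18px;border-radius:9px;background:%s'></span> %s",
            col, cat)
  }, character(1))
  paste(lights, collapse = " &nbsp; ")
}

html_table <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) fmt(x, digits))
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""),
           "</tr>"))
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

render_html <- function(report) {
  s1 <- report$section1_personal
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:13px}",
    ".dial{display:inline-block;text-align:center;margin:4px}</style>",
    sprintf("<title>Risk report %s</title></head><body>", html_escape(s1$player_id)),
    sprintf("<h1>Cutting-biomechanics risk report: %s</h1>", html_escape(s1$player_id)),
    "<h2>1. Personal data</h2>",
    sprintf("<p>Sex: %s; injured limb: %s; trials analyzed: %d of %d.</p>",
            s1$sex, s1$injured_limb, s1$n_trials_analyzed, s1$n_trials_total))
  if (length(s1$excluded_trials)) {
    parts <- c(parts, "<p>Excluded trials:</p><ul>",
               vapply(s1$excluded_trials, function(e)
                 sprintf("<li>%s: %s</li>", html_escape(e$trial),
                         html_escape(e$failure)), character(1)),
               "</ul>")
  }
  for (task in names(report$section2_cod)) {
    cod <- report$section2_cod[[task]]
    parts <- c(parts,
      sprintf("<h2>2. Change of direction — %s</h2>", html_escape(task)),
      sprintf("<p>Mean cut angle %s&deg; (SD %s&deg;)</p>",
              fmt(cod$mean_cut_angle_deg), fmt(cod$sd_cut_angle_deg)),
      html_table(cod$trials))
    perf <- report$section3_performance[[task]]
    parts <- c(parts, sprintf("<h2>3. Performance — %s</h2>", html_escape(task)))
    for (row in perf$trials) {
      dials <- vapply(PERF_METRICS, function(m)
        svg_speedometer(row[[paste0("dial_", m)]],
                        sprintf("%s = %s", m, fmt(row[[m]]))), character(1))
      parts <- c(parts, sprintf("<h4>%s</h4>", html_escape(row$trial)), dials)
    }
    kin <- report$section4_kinematics[[task]]
    parts <- c(parts, sprintf("<h2>4. Kinematics — %s</h2>", html_escape(task)))
    if (!is.null(kin$asymmetry)) {
      for (joint in names(kin$asymmetry)) {
        a <- kin$asymmetry[[joint]]
        parts <- c(parts, svg_asym_bar(joint, a$pct, a$score, a$extreme))
      }
    } else {
      parts <- c(parts, "<p>Asymmetry unavailable (single-limb data).</p>")
    }
    for (frame in c("IC", "pKF")) {
      rk <- report$section5_risk[[task]][[frame]]
      parts <- c(parts,
        sprintf("<h2>5. Risk factors — %s, %s</h2>", html_escape(task), frame),
        svg_risk_pie(rk$summary$factors),
        sprintf("<p>Overall risk in %d of %d trials (%d injured limb, %d non-injured).</p>",
                rk$summary$n_overall_at_risk, rk$summary$n_trials,
                rk$summary$n_overall_injured, rk$summary$n_overall_noninjured),
        "<p>", svg_dashboard(rk$summary$category_red), "</p>",
        html_table(rk$summary$factors))
    }
  }
  parts <- c(parts,
    "<h2>6. Final remarks</h2>",
    sprintf("<p style='border:1px dashed #999;min-height:5em;padding:1em'>%s</p>",
            if (nzchar(report$section6_remarks))
              html_escape(report$section6_remarks)
            else "&nbsp;"),
    "</body></html>")
  paste(parts, collapse = "\n")
}
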