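# Densified behavioral timing for null-calibration sessions: keeps the
# heavy-tailed log-normal form but with an interval median of 3 s so that
# short blocks reliably contain episodes for every partner.
denseTiming <- function() {
  list(
    duration = list(meanlog = log(1.33), sdlog = 0.5),
    interval = list(meanlog = log(3), sdlog = 0.6)
  )
}

fourPartners <- data.frame(
  id = c("f1", "m1", "f2", "m2"),
  sex = c("F", "M", "F", "M")
)

eightPartners <- data.frame(
  id = paste0("p", 1:8),
  sex = rep(c("F", "M"), 4)
)

# deterministic hand-built session for IO and layout tests
tinySession <- function() {
  suppressWarnings(Session(
    subjectId = "r1", subjectSex = "F", area = "S1",
    blocks = data.frame(blockIndex = 1:2, start = c(0, 30), end = c(30, 60)),
    episodes = data.frame(
      onset = c(2, 10, 35), offset = c(3.5, 12, 37),
      partnerId = c("a", "a", "b"), partnerSex = c("F", "F", "M")
    ),
    units = list(
      u1 = c(0.5, 2.2, 2.8, 11.0, 36.2),
      u2 = c(1.0, 34.9, 36.0, 36.5)
    )
  ))
}

# null session (no touch or sex modulation) on the densified timing;
# regenerates until the minimal structure for the requested test is present
nullTouchSession <- function() {
  repeat {
    s <- suppressWarnings(generateSession(
      units = list(u1 = unitTrueBeta()),
      nBlocks = 4, blockLength = 8, partners = fourPartners,
      params = denseTiming()
    ))
    if (nrow(episodes(s)) >= 2) return(s)
  }
}

nullSexSession <- function(blockLength = 10) {
  repeat {
    s <- suppressWarnings(generateSession(
      units = list(u1 = unitTrueBeta()),
      nBlocks = 8, blockLength = blockLength, partners = eightPartners,
      params = denseTiming()
    ))
    ep <- episodes(s)
    if (length(unique(ep$partnerId)) == 8L) return(s)
  }
}
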