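# Two-channel focus taxonomy: site = BRCA1 core, partner = 53BP1.
# Counts: site/partner spot numbers in the assembled structure;
# "inf" = unbounded; encapsulated: null = don't care.
taxonomy: two_channel
min_satellites: 3
min_arc_deg: 180
rules:
  - {site_min: 1, site_max: inf, partner_min: 0, partner_max: 0, encapsulated: null, class: 1}
  - {site_min: 1, site_max: 1, partner_min: 1, partner_max: 1, encapsulated: null, class: 2}
  - {site_min: 2, site_max: inf, partner_min: 1, partner_max: 1, encapsulated: null, class: 3}
  - {site_min: 2, site_max: inf, partner_min: 2, partner_max: inf, encapsulated: null, class: 4}
  - {site_min: 1, site_max: 1, partner_min: 2, partner_max: inf, encapsulated: false, class: 4}
  - {site_min: 1, site_max: 1, partner_min: 2, partner_max: inf, encapsulated: true, class: 5}
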