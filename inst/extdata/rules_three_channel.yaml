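# Three-channel focus taxonomy, RAD51 defined as the structure centre:
# site = RAD51, partner = 53BP1, partner2 = BRCA1.
# This enumeration is a reconstruction: it covers the full count space
# (RAD51 single/multiple x 53BP1 absent/single/multiple x BRCA1
# absent/present, with an encapsulation split) while satisfying the
# pinned definitions: class 4 = multiple RAD51 + multiple 53BP1 without
# BRCA1; classes 7-9 contain all three proteins; class 9 = multiple RAD51
# with BRCA1, encapsulated by multiple 53BP1. Edit freely.
taxonomy: three_channel
min_satellites: 3
min_arc_deg: 180
rules:
  - {site_min: 1, site_max: 1, partner_min: 0, partner_max: 0, partner2_min: 0, partner2_max: 0, encapsulated: null, class: 1}
  - {site_min: 1, site_max: 1, partner_min: 1, partner_max: 1, partner2_min: 0, partner2_max: 0, encapsulated: null, class: 2}
  - {site_min: 1, site_max: 1, partner_min: 2, partner_max: inf, partner2_min: 0, partner2_max: 0, encapsulated: null, class: 3}
  - {site_min: 2, site_max: inf, partner_min: 2, partner_max: inf, partner2_min: 0, partner2_max: 0, encapsulated: null, class: 4}
  - {site_min: 2, site_max: inf, partner_min: 0, partner_max: 0, partner2_min: 0, partner2_max: 0, encapsulated: null, class: 5}
  - {site_min: 1, site_max: inf, partner_min: 0, partner_max: 0, partner2_min: 1, partner2_max: inf, encapsulated: null, class: 6}
  - {site_min: 1, site_max: 1, partner_min: 1, partner_max: inf, partner2_min: 1, partner2_max: inf, encapsulated: null, class: 7}
  - {site_min: 2, site_max: inf, partner_min: 1, partner_max: 1, partner2_min: 1, partner2_max: inf, encapsulated: null, class: 8}
  - {site_min: 2, site_max: inf, partner_min: 2, partner_max: inf, partner2_min: 1, partner2_max: inf, encapsulated: false, class: 8}
  - {site_min: 2, site_max: inf, partner_min: 2, partner_max: inf, partner2_min: 1, partner2_max: inf, encapsulated: true, class: 9}
  - {site_min: 2, site_max: inf, partner_min: 1, partner_max: 1, partner2_min: 0, partner2_max: 0, encapsulated: null, class: 10}
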