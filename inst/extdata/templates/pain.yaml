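# Daily multi-site pain report: header 'P', then intensity/location pairs
# joined by '&'; 'PN' means no pain today.
template_id: pain
kind: pair_list
header: P
intensity_range: [1, 10]
location_vocabulary: [HEAD, CHEST, BELLY, BACK, UL, UR, LL, LR]
no_event_response: PN
valid_example: P2CHEST&3BELLY
description: Daily pain intensity (1-10) and location report
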