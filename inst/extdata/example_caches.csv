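cache_id,study_area,elevation_zone,microsite,x,y,n_seeds_cached,located_y1,n_missing_y1,n_seed_coats_y1,n_germinants_y1,relocated_y2,n_live_seedlings_y2,n_new_germinants_y2
c001,southern,treeline,rock,12.5,30.1,3,TRUE,0,0,2,TRUE,1,0
c002,southern,treeline,no object,45.0,88.2,4,TRUE,4,2,0,,,
c003,southern,treeline,tree,71.3,15.9,2,TRUE,1,1,1,TRUE,0,0
c004,southern,subalpine,rock,22.8,54.6,5,TRUE,2,0,1,TRUE,1,1
c005,southern,subalpine,open,90.4,47.0,1,TRUE,0,0,0,TRUE,0,1
c006,southern,subalpine,tree,63.1,72.5,3,FALSE,,,,,,
c007,northern,treeline,rock,18.9,9.4,6,TRUE,6,3,0,,,
c008,northern,treeline,open,52.7,61.8,3,TRUE,0,0,1,FALSE,,
c009,northern,treeline,tree,80.2,33.3,2,TRUE,0,0,0,TRUE,0,0
c010,northern,subalpine,rock,37.5,20.7,4,TRUE,1,0,2,TRUE,2,0
c011,northern,subalpine,open,66.6,95.1,3,TRUE,3,1,0,,,
c012,northern,subalpine,tree,29.3,78.8,7,TRUE,0,0,3,TRUE,0,0
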