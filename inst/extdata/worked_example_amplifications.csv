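"sample_id","mirna_id","cq","amp_score","cq_conf","flag"
"WX01","wx-miR-01",25,1.5,0.95,"good"
"WX02","wx-miR-01",25,1.5,0.95,"good"
"WX03","wx-miR-01",25,1.5,0.95,"good"
"WX04","wx-miR-01",25,1.5,0.95,"good"
"WX05","wx-miR-01",25,1.5,0.95,"good"
"WX06","wx-miR-01",25,1.5,0.95,"good"
"WX07","wx-miR-01",25,1.5,0.95,"good"
"WX08","wx-miR-01",25,1.5,0.95,"good"
"WX01","wx-miR-02",26,1.5,0.95,"good"
"WX02","wx-miR-02",26,1.5,0.95,"good"
"WX03","wx-miR-02",26,1.5,0.95,"good"
"WX04","wx-miR-02",26,1.5,0.95,"good"
"WX05","wx-miR-02",26,1.5,0.95,"good"
"WX06","wx-miR-02",25,1.5,0.95,"good"
"WX07","wx-miR-02",25,1.5,0.95,"good"
"WX08","wx-miR-02",25,1.5,0.95,"good"
"WX01","wx-miR-03",27,1.5,0.95,"good"
"WX02","wx-miR-03",28,1.5,0.95,"good"
"WX03","wx-miR-03",27,1.5,0.95,"good"
"WX04","wx-miR-03",28,1.5,0.95,"good"
"WX05","wx-miR-03",27,1.5,0.95,"good"
"WX06","wx-miR-03",28,1.5,0.95,"good"
"WX07","wx-miR-03",27,1.5,0.95,"good"
"WX08","wx-miR-03",28,1.5,0.95,"good"
"WX01","wx-miR-04",,1.5,0.95,"censored"
"WX02","wx-miR-04",,1.5,0.95,"censored"
"WX03","wx-miR-04",,1.5,0.95,"censored"
"WX04","wx-miR-04",,1.5,0.95,"censored"
"WX05","wx-miR-04",33,1.5,0.95,"good"
"WX06","wx-miR-04",33,1.5,0.95,"good"
"WX07","wx-miR-04",32,1.5,0.95,"good"
"WX08","wx-miR-04",32,1.5,0.95,"good"
"WX01","wx-miR-05",22,1.5,0.95,"good"
"WX02","wx-miR-05",23,1.5,0.95,"good"
"WX03","wx-miR-05",22,1.5,0.95,"good"
"WX04","wx-miR-05",23,1.5,0.95,"good"
"WX05","wx-miR-05",22,1.5,0.95,"good"
"WX06","wx-miR-05",23,1.5,0.95,"good"
"WX07","wx-miR-05",22,1.5,0.95,"good"
"WX08","wx-miR-05",23,1.5,0.95,"good"
"WX01","wx-miR-06",30,1.5,0.95,"good"
"WX02","wx-miR-06",31,1.5,0.95,"good"
"WX03","wx-miR-06",30,1.5,0.95,"good"
"WX04","wx-miR-06",31,1.5,0.95,"good"
"WX05","wx-miR-06",30,1.5,0.95,"good"
"WX06","wx-miR-06",31,1.5,0.95,"good"
"WX07","wx-miR-06",30,1.5,0.95,"good"
"WX08","wx-miR-06",31,1.5,0.95,"good"
"WX01","wx-miR-07",24,1.5,0.95,"good"
"WX02","wx-miR-07",24.5,1.5,0.95,"good"
"WX03","wx-miR-07",24,1.5,0.95,"good"
"WX04","wx-miR-07",24.5,1.5,0.95,"good"
"WX05","wx-miR-07",24,1.5,0.95,"good"
"WX06","wx-miR-07",24.5,1.5,0.95,"good"
"WX07","wx-miR-07",24,1.5,0.95,"good"
"WX08","wx-miR-07",24.5,1.5,0.95,"good"
"WX01","wx-miR-08",,1.5,0.95,"censored"
"WX02","wx-miR-08",35,1.5,0.95,"censored"
"WX03","wx-miR-08",,1.5,0.95,"censored"
"WX04","wx-miR-08",35,1.5,0.95,"censored"
"WX05","wx-miR-08",,1.5,0.95,"censored"
"WX06","wx-miR-08",35,1.5,0.95,"censored"
"WX07","wx-miR-08",,1.5,0.95,"censored"
"WX08","wx-miR-08",35,1.5,0.95,"censored"
"WX01","wx-miR-09",26,0.5,0.95,"excluded"
"WX02","wx-miR-09",27,1.5,0.95,"good"
"WX03","wx-miR-09",26,1.5,0.95,"good"
"WX04","wx-miR-09",27,1.5,0.95,"good"
"WX05","wx-miR-09",26,1.5,0.95,"good"
"WX06","wx-miR-09",27,1.5,0.95,"good"
"WX07","wx-miR-09",26,1.5,0.95,"good"
"WX08","wx-miR-09",27,1.5,0.95,"good"
"WX01","wx-EC-1",20,1.5,0.95,"good"
"WX02","wx-EC-1",20,1.5,0.95,"good"
"WX03","wx-EC-1",20,1.5,0.95,"good"
"WX04","wx-EC-1",20,1.5,0.95,"good"
"WX05","wx-EC-1",20,1.5,0.95,"good"
"WX06","wx-EC-1",20,1.5,0.95,"good"
"WX07","wx-EC-1",20,1.5,0.95,"good"
"WX08","wx-EC-1",20,1.5,0.95,"good"
"WX01","wx-EC-2",20,1.5,0.95,"good"
"WX02","wx-EC-2",20,1.5,0.95,"good"
"WX03","wx-EC-2",20,1.5,0.95,"good"
"WX04","wx-EC-2",20,1.5,0.95,"good"
"WX05","wx-EC-2",20,1.5,0.95,"good"
"WX06","wx-EC-2",20,1.5,0.95,"good"
"WX07","wx-EC-2",20,1.5,0.95,"good"
"WX08","wx-EC-2",20,1.5,0.95,"good"
"WX01","wx-EC-3",20,1.5,0.95,"good"
"WX02","wx-EC-3",20,1.5,0.95,"good"
"WX03","wx-EC-3",20,1.5,0.95,"good"
"WX04","wx-EC-3",20,1.5,0.95,"good"
"WX05","wx-EC-3",20,1.5,0.95,"good"
"WX06","wx-EC-3",20,1.5,0.95,"good"
"WX07","wx-EC-3",20,1.5,0.95,"good"
"WX08","wx-EC-3",20,1.5,0.95,"good"
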