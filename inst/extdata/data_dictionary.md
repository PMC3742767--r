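# Data dictionary

All coordinates are meters in one local planar frame (no geodesy). Files are
produced by the synthetic-data generator (`analysis/01_simulate.R`) and the
preparation stage; real survey data in the same layout can be substituted.

## effort.csv — survey effort segments (~0.5 km)
| column | description |
|---|---|
| cruise_id | cruise identifier (C01..C27) |
| year, month | cruise calendar entry |
| vessel | Martin / Fulmar / McArthur (nominal 100/200/300-m strips) |
| transect_id | transect identifier within cruise |
| seg_start_km, seg_end_km | along-track bounds of the segment (km from the western terminus) |
| x_start, x_end, y | segment geometry (m) |
| strip_width_m | realized strip width (50-300 m; reduced under poor visibility) |
| seastate | Beaufort sea state 0-6 |
| cloud | cloud cover 0-9 |
| visibility | observer visibility 0-9 |
| swell_m | swell height (m) |
| time | clock time at segment end, numeric hhmmss |

## sightings.csv — seabird sighting groups
| column | description |
|---|---|
| sighting_id | unique record id |
| cruise_id, transect_id | where the group was seen |
| species | WEGU / COMU / CAAU / RHAU / BRAC |
| along_km | along-track position (km) |
| x, y | position (m) |
| group_size | birds in the group |
| behavior | foraging / feeding / sitting / flying / ship-attract; only the first three are analyzed |

## ctd.csv — CTD station records
| column | description |
|---|---|
| cruise_id, station_id | station occupation |
| x, y | station location (m) |
| f1..f6 | fluorescence readings at 1-6 m depth |
| ssf_1_6m | mean fluorescence over the 1-6-m layer (mg/m3) |
| sst | surface temperature at the station (deg C) |
| year | cruise year |

## indices_monthly.csv / upwelling_daily.csv — climate series
Monthly NPGO, PDO, SOI (one row per year x month); daily upwelling index
`ui` by `date`. Bins receive the cruise month's values and the 10-day
trailing mean of `ui` ending on the cruise's last day.

## model_table.csv — the binned model table (one row per 3-km bin)
Bin geometry and effort (`cruise_id`, `year`, `month`, `transect_id`, `bin`,
`start_km`, `end_km`, `length_km`, `x`, `y`, `strip_width_m`, `area_km2`),
detection conditions (`seastate`, `cloud`, `visibility`, `swell_m`, `time`),
per-species counts (`WEGU`..`BRAC`), covariates (`sst`, `sss`, `ssf` with
`ssf_imputed` flag, `dist_land`, `dist_200`, `dist_sefi` in m, `npgo`,
`pdo`, `soi`, `ui`).

## region.geojson / activities.geojson
Planar GeoJSON: the study boundary polygon, colony point, mainland and
200-m-isobath lines; six dominant-use activity footprint polygons with
`activity`, `score` (1-5) and `class` properties.
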