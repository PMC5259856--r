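!Series_title	"Synthetic example series (generated fixture, not a GEO download)"
!Series_geo_accession	"GSE00000"
!Sample_title	"T_rep1"	"T_rep2"	"PX_rep1"	"PX_rep2"
!Sample_geo_accession	"GSM000001"	"GSM000002"	"GSM000003"	"GSM000004"
!series_matrix_table_begin
ID_REF	GSM000001	GSM000002	GSM000003	GSM000004
PR00001	120.5	118.2	240.1	244.9
PR00002	88.0	90.4	91.2	89.9
PR00003	45.3	44.1	12.8	13.5
PR00004	310.7	305.2	308.8	312.4
NC0001	10.1	9.8	10.4	10.0
!series_matrix_table_end
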