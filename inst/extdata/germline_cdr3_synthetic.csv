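gene,segment,cdr3_seq
TCRBJ01-01,J,NTEAFF
TCRBJ01-02,J,NYGYTF
TCRBJ01-03,J,SGNTIYF
TCRBJ01-04,J,TNEKLFF
TCRBJ01-05,J,SNQPQHF
TCRBJ01-06,J,SYNSPLHF
TCRBJ02-01,J,SYNEQFF
TCRBJ02-02,J,NTGELFF
TCRBJ02-03,J,STDTQYF
TCRBJ02-04,J,AKNIQYF
TCRBJ02-05,J,QETQYF
TCRBJ02-06,J,SGANVLTF
TCRBJ02-07,J,SYEQYF
TCRBV01-01,V,CASS
TCRBV02-01,V,CASR
TCRBV03-01,V,CAWS
TCRBV03-02,V,CSAR
TCRBV04-01,V,CAIS
TCRBV04-02,V,CSVE
TCRBV04-03,V,CASG
TCRBV05-01,V,CATS
TCRBV05-02,V,CASS
TCRBV05-03,V,CASR
TCRBV05-04,V,CAWS
TCRBV05-05,V,CSAR
TCRBV05-06,V,CAIS
TCRBV05-07,V,CSVE
TCRBV05-08,V,CASG
TCRBV06-01,V,CATS
TCRBV06-02,V,CASS
TCRBV06-03,V,CASR
TCRBV06-04,V,CAWS
TCRBV06-05,V,CSAR
TCRBV06-06,V,CAIS
TCRBV06-07,V,CSVE
TCRBV06-08,V,CASG
TCRBV06-09,V,CATS
TCRBV07-01,V,CASS
TCRBV07-02,V,CASR
TCRBV07-03,V,CAWS
TCRBV07-04,V,CSAR
TCRBV07-05,V,CAIS
TCRBV07-06,V,CSVE
TCRBV07-07,V,CASG
TCRBV07-08,V,CATS
TCRBV07-09,V,CASS
TCRBV08-01,V,CASR
TCRBV08-02,V,CAWS
TCRBV09-01,V,CSAR
TCRBV10-01,V,CAIS
TCRBV10-02,V,CSVE
TCRBV10-03,V,CASG
TCRBV11-01,V,CATS
TCRBV11-02,V,CASS
TCRBV11-03,V,CASR
TCRBV12-01,V,CAWS
TCRBV12-02,V,CSAR
TCRBV12-03,V,CAIS
TCRBV12-04,V,CSVE
TCRBV12-05,V,CASG
TCRBV13-01,V,CATS
TCRBV14-01,V,CASS
TCRBV15-01,V,CASR
TCRBV16-01,V,CAWS
TCRBV17-01,V,CSAR
TCRBV18-01,V,CAIS
TCRBV19-01,V,CSVE
TCRBV20-01,V,CASG
TCRBV21-01,V,CATS
TCRBV22-01,V,CASS
TCRBV23-01,V,CASR
TCRBV24-01,V,CAWS
TCRBV25-01,V,CSAR
TCRBV26-01,V,CAIS
TCRBV27-01,V,CSVE
TCRBV28-01,V,CASG
TCRBV29-01,V,CATS
TCRBV30-01,V,CASS
TCRBVA-01,V,CASR
TCRBVB-01,V,CAWS
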