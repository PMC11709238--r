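term	category
depression	psychiatric
bipolar	psychiatric
psychosis	psychiatric
schizophrenia	psychiatric
eating disorder	psychiatric
OCD	psychiatric
anxiety disorder	psychiatric
ADHD	psychiatric
PTSD	psychiatric
mania	psychiatric
borderline	psychiatric
back pain	physical
obesity	physical
paralysed	physical
heart disease	physical
cancer	physical
handsome	favourable_attribute
good looking	favourable_attribute
tall	favourable_attribute
olympic gold medallist	very_healthy_control
professional footballer	very_healthy_control
professional tennis player	very_healthy_control
airline pilot	very_healthy_control
marathon runner	very_healthy_control
member of parliament	very_healthy_control
landscape gardener	very_healthy_control
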